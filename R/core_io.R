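#' CKD-EPI 2009 equation coefficients
#'
#' Constants of the 2009 CKD Epidemiology Collaboration creatinine equation.
#' The race multiplier defaults to 1 (i.e. not applied); set
#' `race_factor = 1.159` to reproduce the original equation's Black-race
#' adjustment where a cohort calls for it.
#'
#' @param race_factor Multiplier applied uniformly; default 1 (no race term).
#' @return A list of class `egfr_coefficients`.
#' @examples
#' egfr_coefficients()
#' @export
egfr_coefficients <- function(race_factor = 1) {
  stopifnot(is.numeric(race_factor), race_factor > 0)
  structure(
    list(
      kappa_f = 0.7, kappa_m = 0.9,
      alpha_f = -0.329, alpha_m = -0.411,
      slope = -1.209,
      age_factor = 0.993,
      sex_factor_f = 1.018,
      race_factor = race_factor
    ),
    class = "egfr_coefficients"
  )
}

#' Estimated GFR by the 2009 CKD-EPI creatinine equation
#'
#' @param creatinine Serum creatinine in mg/dL (use
#'   [creatinine_umol_to_mgdl()] for SI-unit inputs). Must be positive.
#' @param age Age in years, positive.
#' @param sex `"F"` or `"M"` (recycled against `creatinine`).
#' @param coeffs Coefficients, see [egfr_coefficients()].
#' @return eGFR in mL/min per 1.73 m^2 (vectorised).
#' @examples
#' ckd_epi_2009(0.7, age = 50, sex = "F")
#' ckd_epi_2009(c(0.9, 2.0), age = 70, sex = "M")
#' @export
ckd_epi_2009 <- function(creatinine, age, sex, coeffs = egfr_coefficients()) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    stop("`creatinine` must be positive and finite (mg/dL)", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("`age` must be positive and finite (years)", call. = FALSE)
  }
  sex <- match_sex(sex)
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)

  kappa <- ifelse(sex == "F", coeffs$kappa_f, coeffs$kappa_m)
  alpha <- ifelse(sex == "F", coeffs$alpha_f, coeffs$alpha_m)
  scr_k <- creatinine / kappa
  egfr <- 141 *
    pmin(scr_k, 1)^alpha *
    pmax(scr_k, 1)^coeffs$slope *
    coeffs$age_factor^age *
    ifelse(sex == "F", coeffs$sex_factor_f, 1) *
    coeffs$race_factor
  unname(egfr)
}

#' Convert serum creatinine from umol/L to mg/dL
#'
#' @param x Creatinine in umol/L.
#' @return Creatinine in mg/dL (`x / 88.42`).
#' @export
creatinine_umol_to_mgdl <- function(x) x / 88.42

# Invert CKD-EPI: serum creatinine (mg/dL) giving a target eGFR. Used by the
# cohort generator so baseline eGFR and the creatinine series stay consistent.
invert_ckd_epi <- function(egfr, age, sex, coeffs = egfr_coefficients()) {
  sex <- match_sex(sex)
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  kappa <- ifelse(sex == "F", coeffs$kappa_f, coeffs$kappa_m)
  alpha <- ifelse(sex == "F", coeffs$alpha_f, coeffs$alpha_m)
  base <- 141 * coeffs$age_factor^age *
    ifelse(sex == "F", coeffs$sex_factor_f, 1) * coeffs$race_factor
  ratio <- egfr / base            # = (scr/kappa)^alpha or ^slope
  # ratio >= 1 <=> scr <= kappa (alpha branch, alpha < 0)
  scr_k <- ifelse(ratio >= 1, ratio^(1 / alpha), ratio^(1 / coeffs$slope))
  unname(kappa * scr_k)
}

match_sex <- function(sex) {
  sex <- toupper(as.character(sex))
  if (!all(sex %in% c("F", "M"))) {
    stop("`sex` must be \"F\" or \"M\"", call. = FALSE)
  }
  sex
}

#' Analyte-to-creatinine ratio
#'
#' Corrects a urinary analyte concentration for urine concentration by
#' dividing by urinary creatinine, e.g. clusterin (ug/L) over creatinine
#' (mmol/L) giving uCCR in ug/mmol.
#'
#' @param analyte Analyte concentration (e.g. ug/L), non-negative.
#' @param creatinine Urinary creatinine (mmol/L), strictly positive.
#' @return `analyte / creatinine` (vectorised).
#' @examples
#' ratio_to_creatinine(1245, 10)  # 124.5 ug/mmol
#' @export
ratio_to_creatinine <- function(analyte, creatinine) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    stop("`creatinine` must be positive and finite", call. = FALSE)
  }
  analyte / creatinine
}

# ---- per-cell classification tables ----------------------------------------

cell_table_mandatory <- c(
  "participant_id", "section_id", "cell_id",
  "epithelial", "p21_nuclear", "ki67_nuclear"
)

#' Read a per-cell classification table
#'
#' Reads a CSV/TSV export of classified cells (one row per cell). Mandatory
#' columns: `participant_id`, `section_id`, `cell_id`, `epithelial`,
#' `p21_nuclear`, `ki67_nuclear`; optional `clusterin_cytoplasmic` for
#' clusterin-panel stains. Marker columns must be encoded 0/1 (`NA` is
#' accepted only in the clusterin column). Unknown columns are preserved.
#'
#' @param path File path.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A data.frame of cells with logical marker columns.
#' @seealso [write_cell_table()]
#' @export
read_cell_table <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  missing_cols <- setdiff(cell_table_mandatory, names(df))
  if (length(missing_cols)) {
    stop("cell table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bool_cols <- intersect(
    c("epithelial", "p21_nuclear", "ki67_nuclear", "clusterin_cytoplasmic"),
    names(df)
  )
  for (col in bool_cols) {
    v <- df[[col]]
    ok <- is.na(v) | v %in% c(0, 1, "0", "1")
    if (!all(ok)) {
      stop("column `", col, "` must be encoded 0/1", call. = FALSE)
    }
    if (anyNA(v) && col != "clusterin_cytoplasmic") {
      stop("column `", col, "` must not contain NA", call. = FALSE)
    }
    df[[col]] <- as.logical(as.integer(v))
  }
  df$participant_id <- as.character(df$participant_id)
  df$section_id <- as.character(df$section_id)
  df$cell_id <- as.character(df$cell_id)
  df
}

#' Write a per-cell classification table
#'
#' Inverse of [read_cell_table()]: logical marker columns are written as 0/1
#' so that `read_cell_table(write_cell_table(x, f))` round-trips.
#'
#' @param cells Data.frame of cells as returned by [read_cell_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, sep = ",") {
  missing_cols <- setdiff(cell_table_mandatory, names(cells))
  if (length(missing_cols)) {
    stop("cell table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- cells
  bool_cols <- intersect(
    c("epithelial", "p21_nuclear", "ki67_nuclear", "clusterin_cytoplasmic"),
    names(out)
  )
  for (col in bool_cols) out[[col]] <- as.integer(out[[col]])
  utils::write.table(out, path, row.names = FALSE, quote = FALSE, sep = sep)
  invisible(path)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All stochastic package functions funnel through this so
# generators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}
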