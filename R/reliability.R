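#' Coefficient of variation
#'
#' `100 * SD / mean` (sample SD, n - 1 denominator) of a subject's repeated
#' measurements, in percent. Undefined (NA) when the mean is zero.
#'
#' @param values Numeric vector of repeated measurements.
#' @return CV in percent, or `NA` for a zero mean.
#' @export
#' @examples
#' coefficient_of_variation(c(9, 10, 11))  # 10
coefficient_of_variation <- function(values) {
  if (length(values) < 2) abort("CV needs at least 2 values.")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * sd(values) / m
}

#' Intraclass correlation coefficient ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, consistency ICC:
#' `(BMS - EMS) / (BMS + (k - 1) EMS)`, where BMS is the between-subject
#' mean square, EMS the residual mean square of the two-way
#' (subject + trial) decomposition, and `k` the number of trials. Quantifies
#' trial-to-trial consistency of a measurement; 1 means trials are perfectly
#' consistent within every subject.
#'
#' @param x Numeric matrix, subjects in rows, trials (repetitions) in
#'   columns; balanced, no missing cells.
#' @return ICC value (`<= 1`), or `NA` when the total variance is zero.
#' @export
#' @examples
#' icc_3_1(matrix(c(1, 3, 5, 2, 4, 6), 3, 2))  # 1: perfectly consistent
icc_3_1 <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("ICC requires a complete (no missing cells) table.")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) abort("ICC needs at least 2 subjects and 2 trials.")
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) return(NA_real_)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- max(ss_total - ss_rows - ss_cols, 0)  # guard rounding below zero
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  if (bms + (k - 1) * ems == 0) return(NA_real_)
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Standard error of measurement from an ICC
#'
#' `SEM = SD * sqrt(1 - ICC)`: the within-subject measurement noise implied
#' by a reliability coefficient. The SD is the between-subject SD of subject
#' means.
#'
#' @param sd Nonnegative standard deviation, in measurement units.
#' @param icc ICC in `[0, 1]`.
#' @return SEM in the same units as `sd`.
#' @export
sem_from_icc <- function(sd, icc) {
  assert_scalar_number(sd, "sd", lower = 0)
  if (!is.numeric(icc) || length(icc) != 1 || is.na(icc) || icc < 0 || icc > 1) {
    abort("`icc` must lie in [0, 1].")
  }
  sd * sqrt(1 - icc)
}

#' Inter-trial reliability report
#'
#' Per-variable reliability of repeated scalar measurements: the cohort mean
#' and SD of per-subject coefficients of variation, ICC(3,1) on the
#' subjects-by-trials table, the SEM derived from the between-subject SD of
#' subject means, and acceptability flags at the conventional thresholds
#' (CV below `cv_thresh` percent and ICC above `icc_thresh`).
#'
#' @param kinematics Tibble with `subject`, `trial`, and one numeric column
#'   per variable, e.g. from [generate_kinematic_trials()].
#' @param cv_thresh CV acceptability threshold in percent (default 10).
#' @param icc_thresh ICC acceptability threshold (default 0.80).
#' @return A tibble with one row per variable: `mean`, `sd`, `cv_mean`,
#'   `cv_sd`, `icc`, `sem`, `acceptable`.
#' @export
reliability_report <- function(kinematics, cv_thresh = 10, icc_thresh = 0.80) {
  vars <- setdiff(names(kinematics), c("subject", "trial"))
  if (length(vars) == 0) abort("`kinematics` has no measurement columns.")
  purrr::map_dfr(vars, function(v) {
    wide <- tidyr::pivot_wider(kinematics[, c("subject", "trial", v)],
                               names_from = "trial",
                               values_from = dplyr::all_of(v))
    mat <- as.matrix(wide[, -1, drop = FALSE])
    cvs <- apply(mat, 1, coefficient_of_variation)
    icc <- icc_3_1(mat)
    subject_means <- rowMeans(mat)
    sd_between <- sd(subject_means)
    sem <- if (!is.na(icc) && icc >= 0) sem_from_icc(sd_between, icc) else NA_real_
    cv_mean <- mean(cvs, na.rm = TRUE)
    tibble(
      variable = v,
      mean = mean(mat),
      sd = sd_between,
      cv_mean = cv_mean,
      cv_sd = sd(cvs, na.rm = TRUE),
      icc = icc,
      sem = sem,
      acceptable = !is.na(icc) && cv_mean < cv_thresh && icc > icc_thresh
    )
  })
}
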