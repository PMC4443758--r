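#' Calcium-cooperativity power-law fit
#'
#' Least-squares line on (log calcium, log quantal content); the slope is
#' the cooperativity exponent (~3 at this synapse). `r_squared` is reported
#' only with >= 3 points.
#'
#' @param points Data.frame with columns `ca_mM` and `qc` (or a two-column
#'   data.frame), all values > 0, >= 2 rows.
#' @return A list of class `cooperativity_fit` with `exponent`, `log_k`,
#'   `r_squared`, `n_points`.
#' @export
cooperativity_fit <- function(points) {
  if (is.data.frame(points)) {
    ca <- if ("ca_mM" %in% names(points)) points$ca_mM else points[[1]]
    qc <- if ("qc" %in% names(points)) points$qc
          else if ("qc_mean" %in% names(points)) points$qc_mean
          else points[[2]]
  } else stop("points must be a data.frame")
  if (length(ca) < 2) stop("need at least 2 points")
  if (any(ca <= 0) || any(qc <= 0))
    stop("calcium and quantal content must be positive for a log-log fit")
  fit <- stats::lm(log(qc) ~ log(ca))
  # r-squared computed directly (summary.lm warns on exact power-law input)
  res <- stats::residuals(fit)
  tot <- sum((log(qc) - mean(log(qc)))^2)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 log_k = unname(stats::coef(fit)[1]),
                 r_squared = if (length(ca) >= 3 && tot > 0)
                   1 - sum(res^2) / tot else NA_real_,
                 n_points = length(ca)),
            class = "cooperativity_fit")
}

#' Homeostasis curve fit: quantal content vs miniature amplitude
#'
#' Fits the population relationship between quantal content and quantal
#' size. The `reciprocal_setpoint` model `QC = E0 / mEPSP` (one parameter,
#' the EPSP set-point, in mV) is what perfect homeostasis implies; the
#' two-parameter `exponential` model `QC = a * exp(b * mEPSP)` is the
#' descriptive alternative. Both report r-squared (on QC) and the predicted
#' EPSP per point (`QC_fit * mEPSP`).
#'
#' @param points Data.frame with columns `mepsp_mean` (or `mepsp_mV`) and
#'   `quantal_content` (or `qc`), >= 3 rows, all positive.
#' @param model `"reciprocal_setpoint"` or `"exponential"`.
#' @return A list of class `homeostasis_fit` with `model`, `params`,
#'   `r_squared`, `predicted_qc`, `predicted_epsp`, `flag`.
#' @export
homeostasis_curve_fit <- function(points,
                                  model = c("reciprocal_setpoint",
                                            "exponential")) {
  model <- match.arg(model)
  m <- if ("mepsp_mean" %in% names(points)) points$mepsp_mean
       else if ("mepsp_mV" %in% names(points)) points$mepsp_mV
       else points[[1]]
  qc <- if ("quantal_content" %in% names(points)) points$quantal_content
        else if ("qc" %in% names(points)) points$qc else points[[2]]
  if (length(m) < 3) stop("need at least 3 points")
  if (any(m <= 0) || any(qc <= 0)) stop("all values must be positive")
  flag <- "none"
  if (model == "reciprocal_setpoint") {
    # least squares for QC = E0/m has the closed form below
    e0 <- sum(qc / m) / sum(1 / m^2)
    pred <- e0 / m
    params <- c(setpoint_mV = e0)
  } else {
    lmfit <- stats::lm(log(qc) ~ m)
    fit <- tryCatch(
      minpack.lm::nlsLM(qc ~ a * exp(b * m),
                        start = list(a = unname(exp(stats::coef(lmfit)[1])),
                                     b = unname(stats::coef(lmfit)[2]))),
      error = function(e) NULL)
    if (is.null(fit)) {
      flag <- "fit_failure"
      pred <- exp(stats::fitted(lmfit))
      params <- c(a = unname(exp(stats::coef(lmfit)[1])),
                  b = unname(stats::coef(lmfit)[2]))
    } else {
      pred <- stats::predict(fit)
      params <- stats::coef(fit)
    }
  }
  ss_res <- sum((qc - pred)^2)
  ss_tot <- sum((qc - mean(qc))^2)
  structure(list(model = model, params = params,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot
                             else NA_real_,
                 predicted_qc = pred, predicted_epsp = pred * m,
                 flag = flag),
            class = "homeostasis_fit")
}

#' Predicted percent decrease in release from a calcium drop
#'
#' Under the power-law release model, release scales as
#' `calcium^exponent`, so reducing the presynaptic calcium signal to
#' `ca_fraction` of its baseline predicts a release decrease of
#' `100 * (1 - ca_fraction^exponent)` percent. With exponent 3, a 50% drop
#' in calcium predicts an 87.5% drop in release.
#'
#' @param ca_fraction Remaining fraction of the calcium signal, in (0, 1].
#' @param exponent Power-law exponent, > 0.
#' @return Predicted percent decrease in release.
#' @export
predicted_release_change <- function(ca_fraction, exponent) {
  stopifnot(ca_fraction > 0, ca_fraction <= 1, exponent > 0)
  100 * (1 - ca_fraction^exponent)
}

#' Two-sample group comparison (Student's t-test)
#'
#' Two-sided two-sample t-test, pooled variance by default (Welch by flag),
#' with group means and SEMs.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance test.
#' @return A list of class `group_comparison` with `group_means`, `sems`,
#'   `t_stat`, `p_value`, `n`.
#' @export
group_compare <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(a, b, var.equal = !welch)
  structure(list(group_means = c(mean(a), mean(b)),
                 sems = c(stats::sd(a) / sqrt(length(a)),
                          stats::sd(b) / sqrt(length(b))),
                 t_stat = unname(tt$statistic),
                 p_value = tt$p.value,
                 n = c(length(a), length(b))),
            class = "group_comparison")
}
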