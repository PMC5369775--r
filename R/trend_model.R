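# Risk vs number of risk factors: logistic trend of a binary outcome on the
# per-subject risk-factor count, and the stratified risk-ratio-by-count
# curve.

#' Number of risk factors per subject
#'
#' @param factors risk_factor_matrix.
#' @return integer vector of row sums (0..J).
#' @export
count_risk_factors <- function(factors) {
  as.integer(rowSums(factors))
}

#' Logistic trend of outcome risk on risk-factor count
#'
#' Maximum-likelihood logistic regression (IRLS) of the binary outcome on
#' the risk-factor count, with a Wald p-value for the slope (per additional
#' risk factor, log-odds scale). Complete or quasi-complete separation,
#' where the MLE diverges, is reported through `converged = FALSE` rather
#' than an error.
#'
#' @param counts per-subject risk-factor counts.
#' @param outcome binary vector of the same length; both classes present.
#' @return object of class `trend_fit` with `intercept`, `slope`, `se`,
#'   `p_value`, `n`, `converged`.
#' @export
fit_logistic_trend <- function(counts, outcome) {
  stopifnot(length(counts) == length(outcome),
            all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2L)
    stop_("fit_logistic_trend: outcome must contain both classes")
  fit <- suppressWarnings(
    stats::glm(outcome ~ counts, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100L)))
  co <- summary(fit)$coefficients
  slope <- co["counts", "Estimate"]
  se <- co["counts", "Std. Error"]
  # diverging coefficients or huge SE flag separation
  converged <- fit$converged && is.finite(slope) && is.finite(se) &&
    abs(slope) < 30 && se < 1e3
  structure(list(intercept = co["(Intercept)", "Estimate"],
                 slope = slope, se = se,
                 p_value = 2 * stats::pnorm(-abs(slope / se)),
                 n = length(outcome), converged = converged),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic trend (n = %d): slope b = %.4f (se %.4f), Wald p = %.4f%s\n",
    x$n, x$slope, x$se, x$p_value,
    if (x$converged) "" else " [NOT converged / separation]"))
  invisible(x)
}

#' Risk ratio by number of risk factors
#'
#' For each observed risk-factor count, the stratum size, event count, and
#' the risk ratio relative to the reference rate with exact
#' (Clopper-Pearson) bounds.
#'
#' @param counts per-subject risk-factor counts.
#' @param outcome binary outcome vector.
#' @param p0 reference-population rate of the outcome.
#' @param conf confidence level.
#' @return data.frame sorted by count with columns `count`, `n`, `k`, `rr`,
#'   `ci_low`, `ci_high`.
#' @export
rr_by_count <- function(counts, outcome, p0, conf = 0.95) {
  stopifnot(length(counts) == length(outcome), all(outcome %in% c(0, 1)))
  vals <- sort(unique(counts))
  rows <- lapply(vals, function(v) {
    idx <- counts == v
    n <- sum(idx)
    k <- sum(outcome[idx])
    rr <- risk_ratio(k, n, p0, conf)
    data.frame(count = v, n = n, k = k, rr = rr$rr,
               ci_low = rr$low, ci_high = rr$high)
  })
  do.call(rbind, rows)
}
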