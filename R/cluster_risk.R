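# Cluster-specific outcome risk ratios relative to general-population
# reference rates: exact binomial (Clopper-Pearson) inference, two-sided
# exact p-values, and multiplicity control across the cluster x outcome grid.

#' General-population reference rates
#'
#' Baseline outcome probabilities in the reference (general pregnant)
#' population, against which cluster risks are standardized. Preeclampsia
#' subtype rates are expressed as fractions of the overall preeclampsia rate:
#' severity (`severe_frac`) and delivery timing (`early_frac`,
#' `intermediate_frac`, `term_frac`; `preterm_frac` = early + intermediate
#' timing, i.e. delivery before 37 weeks).
#'
#' Defaults are Finnish national register estimates (Medical Birth Register
#' and Care Register for Health Care, 2013): preeclampsia 2.5%, of which 24%
#' severe, 8% early-onset, 15% intermediate, 77% term, 23% preterm;
#' gestational hypertension 4.4%; SGA 2.3%; gestational diabetes 9%.
#'
#' @param pe baseline probability of preeclampsia.
#' @param severe_frac fraction of preeclampsia cases that are severe.
#' @param early_frac,intermediate_frac,term_frac,preterm_frac timing
#'   fractions of preeclampsia cases; term + preterm must equal 1 and
#'   early + intermediate must not exceed preterm.
#' @param gh,sga,gdm baseline probabilities of gestational hypertension,
#'   small-for-gestational-age birth and gestational diabetes.
#' @return object of class `reference_rates`.
#' @export
reference_rates <- function(pe = 0.025, severe_frac = 0.24,
                            early_frac = 0.08, intermediate_frac = 0.15,
                            term_frac = 0.77, preterm_frac = 0.23,
                            gh = 0.044, sga = 0.023, gdm = 0.09) {
  p0 <- c(pe = pe, gh = gh, sga = sga, gdm = gdm)
  if (any(p0 <= 0 | p0 >= 1))
    stop_("reference_rates: baseline probabilities must lie in (0,1)")
  fr <- c(severe_frac = severe_frac, early_frac = early_frac,
          intermediate_frac = intermediate_frac, term_frac = term_frac,
          preterm_frac = preterm_frac)
  if (any(fr < 0 | fr > 1))
    stop_("reference_rates: subtype fractions must lie in [0,1]")
  if (abs(term_frac + preterm_frac - 1) > 1e-9)
    stop_("reference_rates: term_frac + preterm_frac must equal 1")
  if (early_frac + intermediate_frac > preterm_frac + 1e-9)
    stop_("reference_rates: early + intermediate fractions exceed preterm")
  structure(list(pe = pe, severe_frac = severe_frac, early_frac = early_frac,
                 intermediate_frac = intermediate_frac, term_frac = term_frac,
                 preterm_frac = preterm_frac, gh = gh, sga = sga, gdm = gdm),
            class = "reference_rates")
}

#' Default Finnish-register reference rates
#'
#' @return `reference_rates` object with the package defaults.
#' @export
predo_reference_rates <- function() reference_rates()

#' Read reference rates from a YAML file
#'
#' The file holds the fields of [reference_rates()] (`pe`, `severe_frac`,
#' `early_frac`, `intermediate_frac`, `term_frac`, `preterm_frac`, `gh`,
#' `sga`, `gdm`); omitted fields fall back to the package defaults. An
#' example mirroring the defaults ships as
#' `system.file("extdata", "reference_rates.yaml", package = "riskclust")`.
#'
#' @param path YAML file path.
#' @return `reference_rates` object.
#' @export
read_reference_rates <- function(path) {
  if (!file.exists(path)) stop_("read_reference_rates: file not found: ", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(reference_rates))
  extra <- setdiff(names(vals), allowed)
  if (length(extra))
    stop_("read_reference_rates: unknown field(s): ",
          paste(extra, collapse = ", "))
  do.call(reference_rates, vals)
}

#' Expand subtype fractions into per-outcome baseline rates
#'
#' Subtype baseline rates are exact products of the overall preeclampsia rate
#' and the subtype fractions (no intermediate rounding), e.g.
#' `p0(severe_pe) = p0(pe) * severe_frac`. Individual outcomes can be
#' overridden, e.g. to use pre-rounded register sub-rates.
#'
#' @param ref reference_rates object.
#' @param override optional named numeric vector of per-outcome baseline
#'   rates replacing the computed defaults.
#' @return named numeric vector of baseline probabilities for the standard
#'   outcome set ([standard_outcomes()]).
#' @export
expand_subtype_rates <- function(ref, override = NULL) {
  stopifnot(inherits(ref, "reference_rates"))
  p0 <- c(pe              = ref$pe,
          severe_pe       = ref$pe * ref$severe_frac,
          early_pe        = ref$pe * ref$early_frac,
          intermediate_pe = ref$pe * ref$intermediate_frac,
          term_pe         = ref$pe * ref$term_frac,
          preterm_pe      = ref$pe * ref$preterm_frac,
          gh              = ref$gh,
          sga             = ref$sga,
          gdm             = ref$gdm)
  if (!is.null(override)) {
    stopifnot(!is.null(names(override)), all(names(override) %in% names(p0)))
    p0[names(override)] <- override
  }
  p0
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion, obtained by inverting
#' the binomial tail probabilities (equivalently, beta quantiles). At k = 0
#' the lower bound is 0; at k = n the upper bound is 1.
#'
#' @param k number of events (vectorized).
#' @param n number of trials.
#' @param conf confidence level in (0,1).
#' @return data.frame with columns `low` and `high`.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n), conf > 0, conf < 1)
  alpha <- 1 - conf
  low  <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  data.frame(low = low, high = high)
}

#' Two-sided exact binomial p-value
#'
#' Probability, under Binomial(n, p0), of all outcomes at most as likely as
#' the observed k (minimum-likelihood two-sided convention, with a 1 + 1e-7
#' relative tolerance on the density comparison). Returns a value in (0, 1].
#'
#' @param k observed number of events.
#' @param n number of trials.
#' @param p0 null event probability in (0,1).
#' @return p-value.
#' @export
exact_binom_p <- function(k, n, p0) {
  stopifnot(length(k) == 1, k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  d <- stats::dbinom(k, n, p0)
  dd <- stats::dbinom(0:n, n, p0)
  p <- sum(dd[dd <= d * (1 + 1e-7)])
  max(min(p, 1), stats::dbinom(k, n, p0))
}

#' Risk ratio with exact confidence bounds
#'
#' Point estimate `(k/n) / p0` and 95% bounds from the Clopper-Pearson
#' interval on k/n divided by the reference rate p0.
#'
#' @inheritParams exact_binom_p
#' @param conf confidence level.
#' @return list with `rr`, `low`, `high` (unrounded).
#' @export
risk_ratio <- function(k, n, p0, conf = 0.95) {
  stopifnot(p0 > 0, p0 < 1)
  ci <- clopper_pearson(k, n, conf)
  list(rr = (k / n) / p0, low = ci$low / p0, high = ci$high / p0)
}

#' Format a risk ratio or bound for reporting
#'
#' Reporting convention: one decimal, except values below 0.1 (and above 0)
#' which are shown to two decimals so small lower bounds remain visible.
#'
#' @param x numeric vector of RRs or bounds.
#' @return numeric vector rounded for display.
#' @export
format_rr <- function(x) {
  ifelse(x > 0 & x < 0.1, round_half_up(x, 2), round_half_up(x, 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across a family of tests.
#'
#' @param p_values numeric vector of p-values in (0,1].
#' @return vector of q-values, order-preserving, each >= its p, capped at 1.
#' @export
adjust_bh <- function(p_values) {
  if (!length(p_values)) stop_("adjust_bh: empty p-value list")
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha family-wise error level.
#' @param n_clusters,n_outcomes grid dimensions.
#' @return `alpha / (n_clusters * n_outcomes)`.
#' @export
bonferroni_threshold <- function(alpha, n_clusters, n_outcomes) {
  stopifnot(n_clusters >= 1, n_outcomes >= 1)
  alpha / (n_clusters * n_outcomes)
}

#' Risk-ratio table across the cluster x outcome grid
#'
#' For every (cluster, outcome) cell: the cluster size n, event count k, risk
#' ratio relative to the reference rate with exact confidence bounds, the
#' two-sided exact binomial p-value, the BH q-value (adjusted jointly across
#' the whole grid), and nominal / Bonferroni significance flags.
#'
#' @param partition `partition` object aligned with `outcomes`.
#' @param outcomes outcome_matrix.
#' @param ref reference_rates object, or a named numeric vector of baseline
#'   probabilities covering the outcome columns.
#' @param conf confidence level for the RR bounds.
#' @param alpha significance level for both flags.
#' @param override passed to [expand_subtype_rates()] when `ref` is a
#'   reference_rates object.
#' @return data.frame with one row per (cluster, outcome).
#' @export
compute_risk_table <- function(partition, outcomes, ref = predo_reference_rates(),
                               conf = 0.95, alpha = 0.05, override = NULL) {
  stopifnot(inherits(partition, "partition"))
  if (length(partition$labels) != nrow(outcomes))
    stop_("compute_risk_table: partition and outcome matrix are misaligned")
  p0 <- if (inherits(ref, "reference_rates"))
    expand_subtype_rates(ref, override) else ref
  missing_p0 <- setdiff(colnames(outcomes), names(p0))
  if (length(missing_p0))
    stop_("compute_risk_table: no reference rate for outcome(s): ",
          paste(missing_p0, collapse = ", "))
  K <- partition$K
  M <- ncol(outcomes)
  rows <- vector("list", K * M)
  i <- 0L
  for (c_ in seq_len(K)) {
    idx <- partition$labels == c_
    n_c <- sum(idx)
    for (m in colnames(outcomes)) {
      k <- sum(outcomes[idx, m])
      rr <- risk_ratio(k, n_c, p0[[m]], conf)
      i <- i + 1L
      rows[[i]] <- data.frame(
        cluster = c_, outcome = m, n = n_c, k = k,
        rr = rr$rr, ci_low = rr$low, ci_high = rr$high,
        p_value = exact_binom_p(k, n_c, p0[[m]]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$q_value <- adjust_bh(tab$p_value)
  tab$significant_nominal <- tab$p_value < alpha
  tab$significant_bonferroni <- tab$p_value < bonferroni_threshold(alpha, K, M)
  tab
}
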