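# Synthetic cohort generator: Bernoulli-mixture risk-factor profiles with
# known latent clusters and cluster-dependent outcome risks, so clustering
# recovery and risk-ratio estimation can be validated end to end.

#' Configuration for the synthetic cohort generator
#'
#' Subjects are drawn from `K*` latent clusters (`cluster_weights`); risk
#' factor j of a subject in cluster c is Bernoulli(`prototype_matrix[c, j]`).
#' Outcomes: total preeclampsia, gestational hypertension, SGA and
#' gestational diabetes are Bernoulli with probability
#' `rr * p0` (`cluster_outcome_rr` times the reference rate). Preeclampsia
#' subtypes are generated hierarchically: given a preeclampsia case, delivery
#' timing (early / intermediate / term) is multinomial with probabilities
#' proportional to the reference timing fractions scaled by the cluster's
#' subtype multipliers, and severity is Bernoulli with the severity fraction
#' times its multiplier; `preterm_pe` is derived as early-or-intermediate.
#' This guarantees the subtype hierarchy by construction while preserving
#' the targeted cluster-specific risks.
#'
#' `cluster_outcome_rr` is a `K* x 8` matrix with columns `pe`, `severe_pe`,
#' `early_pe`, `intermediate_pe`, `term_pe`, `gh`, `sga`, `gdm`: risk-ratio
#' multipliers on the reference rate for `pe`, `gh`, `sga`, `gdm`, and
#' within-case multipliers on the subtype fractions for the preeclampsia
#' subtype columns.
#'
#' @param n_subjects cohort size.
#' @param cluster_weights probabilities of the latent clusters (sum to 1).
#' @param prototype_matrix `K* x J` per-cluster Bernoulli probabilities,
#'   with risk-factor column names.
#' @param outcome_reference reference_rates object.
#' @param cluster_outcome_rr multiplier matrix as described above.
#' @param seed integer seed for the generator's private RNG stream.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 903L, cluster_weights,
                             prototype_matrix,
                             outcome_reference = predo_reference_rates(),
                             cluster_outcome_rr, seed = NULL) {
  stopifnot(n_subjects >= 1)
  K <- length(cluster_weights)
  if (abs(sum(cluster_weights) - 1) > 1e-9)
    stop_("generator_config: cluster weights must sum to 1")
  if (any(cluster_weights < 0))
    stop_("generator_config: negative cluster weight")
  prototype_matrix <- as.matrix(prototype_matrix)
  if (nrow(prototype_matrix) != K)
    stop_("generator_config: prototype rows must match the number of clusters")
  if (any(prototype_matrix < 0 | prototype_matrix > 1))
    stop_("generator_config: prototype probabilities must lie in [0,1]")
  cluster_outcome_rr <- as.matrix(cluster_outcome_rr)
  need <- c("pe", "severe_pe", "early_pe", "intermediate_pe", "term_pe",
            "gh", "sga", "gdm")
  if (!all(need %in% colnames(cluster_outcome_rr)))
    stop_("generator_config: cluster_outcome_rr must have columns ",
          paste(need, collapse = ", "))
  if (nrow(cluster_outcome_rr) != K)
    stop_("generator_config: rr rows must match the number of clusters")
  if (any(cluster_outcome_rr < 0))
    stop_("generator_config: negative risk multiplier")
  ref <- outcome_reference
  for (m in c("pe", "gh", "sga", "gdm"))
    if (any(cluster_outcome_rr[, m] * ref[[m]] > 1 + 1e-12))
      stop_("generator_config: rr * p0 exceeds 1 for outcome ", m)
  if (any(cluster_outcome_rr[, "severe_pe"] * ref$severe_frac > 1 + 1e-12))
    stop_("generator_config: severity multiplier exceeds 1/severe_frac")
  structure(list(n_subjects = as.integer(n_subjects),
                 cluster_weights = cluster_weights,
                 prototype_matrix = prototype_matrix,
                 outcome_reference = ref,
                 cluster_outcome_rr = cluster_outcome_rr,
                 seed = seed),
            class = "generator_config")
}

#' True per-cluster outcome probabilities implied by a generator config
#'
#' @param config generator_config.
#' @return `K* x 9` matrix of event probabilities for the standard outcome
#'   set (including the derived `preterm_pe`).
#' @export
true_outcome_rates <- function(config) {
  ref <- config$outcome_reference
  rr <- config$cluster_outcome_rr
  K <- nrow(rr)
  p_pe <- pmin(1, rr[, "pe"] * ref$pe)
  tim <- cbind(early        = ref$early_frac * rr[, "early_pe"],
               intermediate = ref$intermediate_frac * rr[, "intermediate_pe"],
               term         = ref$term_frac * rr[, "term_pe"])
  tim <- tim / rowSums(tim)
  p_sev <- pmin(1, ref$severe_frac * rr[, "severe_pe"])
  out <- cbind(pe              = p_pe,
               severe_pe       = p_pe * p_sev,
               early_pe        = p_pe * tim[, "early"],
               intermediate_pe = p_pe * tim[, "intermediate"],
               term_pe         = p_pe * tim[, "term"],
               preterm_pe      = p_pe * (tim[, "early"] + tim[, "intermediate"]),
               gh              = pmin(1, rr[, "gh"] * ref$gh),
               sga             = pmin(1, rr[, "sga"] * ref$sga),
               gdm             = pmin(1, rr[, "gdm"] * ref$gdm))
  rownames(out) <- rownames(rr)
  out
}

#' Generate a synthetic cohort
#'
#' Draws latent cluster assignments, risk-factor profiles and outcomes as
#' described in [generator_config()]. Identical seeds give identical
#' cohorts; the caller's RNG state is untouched.
#'
#' @param config generator_config.
#' @return list with `factors` (risk_factor_matrix), `outcomes`
#'   (outcome_matrix over [standard_outcomes()]), `truth` (the latent
#'   `partition`, canonically labelled), and `truth_clusters` (for each
#'   truth label, the corresponding row of the config's prototype and
#'   risk-multiplier matrices; generator clusters that drew no subject are
#'   absent).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  J <- ncol(config$prototype_matrix)
  ref <- config$outcome_reference
  rr <- config$cluster_outcome_rr
  with_seed(config$seed, {
    z <- sample.int(length(config$cluster_weights), n, replace = TRUE,
                    prob = config$cluster_weights)
    X <- matrix(stats::rbinom(n * J, 1L, config$prototype_matrix[z, ]),
                nrow = n, ncol = J)
    colnames(X) <- colnames(config$prototype_matrix)

    pe <- stats::rbinom(n, 1L, pmin(1, rr[z, "pe"] * ref$pe))
    # timing of delivery among cases: reference fractions scaled by the
    # cluster multipliers, renormalized per cluster
    tw <- cbind(ref$early_frac * rr[z, "early_pe"],
                ref$intermediate_frac * rr[z, "intermediate_pe"],
                ref$term_frac * rr[z, "term_pe"])
    tw <- tw / rowSums(tw)
    u <- stats::runif(n)
    timing <- 1L + (u > tw[, 1L]) + (u > tw[, 1L] + tw[, 2L])
    early <- as.integer(pe == 1L & timing == 1L)
    inter <- as.integer(pe == 1L & timing == 2L)
    term  <- as.integer(pe == 1L & timing == 3L)
    preterm <- as.integer(early | inter)
    severe <- as.integer(pe == 1L &
      stats::rbinom(n, 1L, pmin(1, ref$severe_frac * rr[z, "severe_pe"])) == 1L)

    gh  <- stats::rbinom(n, 1L, pmin(1, rr[z, "gh"] * ref$gh))
    sga <- stats::rbinom(n, 1L, pmin(1, rr[z, "sga"] * ref$sga))
    gdm <- stats::rbinom(n, 1L, pmin(1, rr[z, "gdm"] * ref$gdm))

    Y <- cbind(pe = pe, severe_pe = severe, early_pe = early,
               intermediate_pe = inter, term_pe = term,
               preterm_pe = preterm, gh = gh, sga = sga, gdm = gdm)
    ids <- sprintf("S%04d", seq_len(n))
    rownames(X) <- rownames(Y) <- ids
    list(factors  = suppressWarnings(risk_factor_matrix(X)),
         outcomes = outcome_matrix(Y),
         truth    = partition(z),
         truth_clusters = unique(z))
  })
}

#' Default cohort configuration emulating the study population
#'
#' Eleven latent groups defined as risk-factor combinations: the defining
#' factors of a group are deterministic (probability 1), excluded factors
#' are absent, and "partial" factors carried by only a fraction of the
#' group's members have intermediate probabilities — mirroring how
#' risk-factor clusters in a high-risk antenatal cohort are constituted
#' (previous preeclampsia alone or with obesity, obesity alone, advanced
#' age alone or with obesity, chronic hypertension, previous SGA birth,
#' gestational diabetes, a mixed group of rarer factors, previous fetal
#' demise, diet-treated GDM alone).
#'
#' The implied risk-factor marginals match the study cohort of 903
#' high-risk pregnant women (previous preeclampsia ~25%, chronic
#' hypertension ~15%, BMI>30 ~39%, age>40 ~16.5%, ...) and the pooled
#' outcome prevalences match the observed diagnoses (total preeclampsia
#' ~9.5-10.5%, severe ~4%, early-onset ~1%). Group-specific preeclampsia
#' risk ratios span the observed range (0.8 for isolated advanced age up to
#' ~10 for previous preeclampsia with obesity). About 1% of generated
#' subjects carry no risk factor (members of partial-factor groups).
#'
#' @param n_subjects cohort size (default 903).
#' @param seed generator seed.
#' @return generator_config.
#' @export
predo_default_config <- function(n_subjects = 903L, seed = NULL) {
  factors <- c("pe_prev", "sga_prev", "chtn", "gdm_diet", "gdm_ins",
               "bmi30", "age_lt20", "age_gt40", "sle", "sjogren",
               "t1d", "demise")
  w <- c(0.140, 0.090, 0.235, 0.110, 0.045, 0.115, 0.100, 0.035, 0.060,
         0.025, 0.045)
  proto <- rbind(
    c(1,    0,    0,    0,    0,    0,    0,    0, 0,     0,    0,    0),
    c(1,    0.02, 0.15, 0,    0,    1,    0,    0, 0,     0,    0,    0),
    c(0,    0,    0,    0.04, 0,    1,    0,    0, 0,     0,    0,    0),
    c(0,    0.08, 0,    0,    0,    0,    0,    1, 0,     0,    0,    0),
    c(0,    0,    0.10, 0,    0,    1,    0,    1, 0,     0,    0,    0),
    c(0.15, 0,    1,    0.08, 0,    0.30, 0,    0.05, 0,  0,    0,    0),
    c(0,    1,    0,    0,    0,    0,    0,    0, 0,     0,    0,    0.10),
    c(0,    0,    0.30, 1,    0.35, 0.25, 0,    0, 0,     0,    0,    0),
    c(0,    0,    0,    0,    0.02, 0.10, 0.48, 0, 0.073, 0.24, 0.33, 0.10),
    c(0,    0,    0,    0.20, 0,    0,    0,    0, 0,     0,    0,    1),
    c(0,    0,    0,    1,    0,    0.20, 0,    0, 0,     0,    0,    0))
  colnames(proto) <- factors
  rownames(proto) <- paste0("G", seq_len(nrow(proto)))
  rr <- cbind(
    pe              = c(8, 10, 2.1, 0.8, 3, 5.5, 2.5, 7.3, 3, 3.1, 1.1),
    severe_pe       = c(1.5, 1.5, 1.6, 1.0, 1.5, 2.5, 2.0, 1.0, 1.8, 1.5, 1.0),
    early_pe        = c(1.2, 1.0, 0.5, 0.5, 1.0, 2.5, 3.0, 1.0, 2.0, 1.0, 0.5),
    intermediate_pe = c(1.2, 1.2, 0.7, 0.8, 1.2, 2.0, 1.5, 1.0, 1.5, 1.0, 0.7),
    term_pe         = rep(1, 11),
    gh              = rep(2.4, 11),
    sga             = c(1.2, 1.2, 1.2, 1.2, 1.2, 2, 4, 1.2, 1.2, 2, 1),
    gdm             = c(2, 2, 3.2, 2.5, 2.5, 2, 1.5, 3.5, 3, 2, 3.5))
  rownames(rr) <- rownames(proto)
  generator_config(n_subjects = n_subjects, cluster_weights = w,
                   prototype_matrix = proto,
                   outcome_reference = predo_reference_rates(),
                   cluster_outcome_rr = rr, seed = seed)
}
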