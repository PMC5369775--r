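test_that("subtype reference rates are exact products of the quoted fractions", {
  p0 <- expand_subtype_rates(predo_reference_rates())
  expect_equal(p0[["pe"]], 0.025)
  expect_equal(p0[["severe_pe"]], 0.025 * 0.24)  # 0.006
  expect_equal(p0[["early_pe"]], 0.025 * 0.08)   # 0.002
  expect_equal(p0[["intermediate_pe"]], 0.025 * 0.15)
  expect_equal(p0[["term_pe"]] + p0[["preterm_pe"]], 0.025)
  expect_equal(p0[["gh"]], 0.044)
  expect_equal(p0[["sga"]], 0.023)
  expect_equal(p0[["gdm"]], 0.09)

  over <- expand_subtype_rates(predo_reference_rates(),
                               override = c(term_pe = 0.019))
  expect_equal(over[["term_pe"]], 0.019)
  expect_equal(over[["pe"]], 0.025)

  expect_error(reference_rates(term_frac = 0.5, preterm_frac = 0.4),
               "must equal 1")
  expect_error(reference_rates(early_frac = 0.2, intermediate_frac = 0.1),
               "exceed preterm")
})

test_that("reference rates read from YAML match the constructor", {
  path <- system.file("extdata", "reference_rates.yaml", package = "riskclust")
  ref <- read_reference_rates(path)
  expect_identical(unclass(ref), unclass(predo_reference_rates()))

  partial <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pe = 0.03), partial)
  expect_equal(read_reference_rates(partial)$pe, 0.03)
  expect_equal(read_reference_rates(partial)$gh, 0.044)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pe = 0.03, ghx = 1), bad)
  expect_error(read_reference_rates(bad), "unknown field")
})

test_that("Clopper-Pearson bounds match the closed forms and binom.test", {
  ci <- clopper_pearson(0, 13)
  expect_equal(ci$low, 0)
  expect_equal(ci$high, 1 - (0.025)^(1 / 13), tolerance = 1e-12)  # 0.24705

  expect_equal(clopper_pearson(13, 13)$high, 1)
  expect_equal(clopper_pearson(13, 13)$low, (0.025)^(1 / 13), tolerance = 1e-12)

  ci <- clopper_pearson(1, 102)
  expect_equal(ci$low, 0.000248, tolerance = 1e-3)
  # beta-quantile oracle for the upper bound of the k=1, n=102 cell
  expect_equal(ci$high, qbeta(0.975, 2, 101), tolerance = 1e-12)
  expect_equal(round_half_up(ci$high / 0.025, 1), 2.1)

  # independent oracle: binom.test's conf.int across a grid
  for (n in c(5, 37, 120)) for (k in unique(c(0, 1, n %/% 3, n))) {
    expect_equal(unname(unlist(clopper_pearson(k, n, 0.95))),
                 as.numeric(binom.test(k, n)$conf.int),
                 tolerance = 1e-12, label = sprintf("CP k=%d n=%d", k, n))
  }
})

test_that("exact binomial p-value follows the minimum-likelihood convention", {
  # k at the mode: every outcome is at most as likely, so p = 1
  expect_equal(exact_binom_p(0, 13, 0.025), 1)
  # brute-force enumeration oracle
  expect_equal(exact_binom_p(27, 138, 0.025), oracle_binom_p(27, 138, 0.025),
               tolerance = 1e-12)
  # extreme tail: tiny but strictly positive
  p <- exact_binom_p(138, 138, 0.025)
  expect_lt(p, 1e-100)
  expect_gt(p, 0)

  # agreement with binom.test across a spot-check grid up to n = 500
  set.seed(3)
  for (i in 1:25) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.005, 0.6)
    expect_equal(exact_binom_p(k, n, p0),
                 binom.test(k, n, p0)$p.value, tolerance = 1e-12,
                 label = sprintf("p-value k=%d n=%d p0=%.3f", k, n, p0))
  }
})

test_that("risk ratios with reporting rounding reproduce reference-table rows", {
  # cluster with k=1 of n=102 at baseline 2.5%
  rr <- risk_ratio(1, 102, 0.025)
  expect_equal(format_rr(rr$rr), 0.4)
  expect_equal(format_rr(rr$low), 0.01)
  expect_equal(format_rr(rr$high), 2.1)

  # zero-event cluster of 13: upper bounds across baseline rates
  rr_pe <- risk_ratio(0, 13, 0.025)
  expect_equal(rr_pe$rr, 0)
  expect_equal(rr_pe$low, 0)
  expect_equal(format_rr(rr_pe$high), 9.9)
  expect_equal(format_rr(risk_ratio(0, 13, 0.025 * 0.24)$high), 41.2)
  expect_equal(format_rr(risk_ratio(0, 13, 0.025 * 0.08)$high), 123.5)

  # identity when the observed proportion equals the baseline
  expect_equal(risk_ratio(25, 1000, 0.025)$rr, 1)
})

test_that("risk ratio point estimate always lies inside its interval and grows with k", {
  for (n in c(10, 50, 200)) {
    prev <- -1
    for (k in 0:n) {
      rr <- risk_ratio(k, n, 0.05)
      expect_gte(rr$rr, rr$low)
      expect_lte(rr$rr, rr$high)
      expect_gte(rr$rr, prev)
      prev <- rr$rr
    }
  }
})

test_that("Clopper-Pearson empirical coverage meets the nominal level", {
  set.seed(1234)
  reps <- 10000
  for (n in c(10, 50, 200)) for (p in c(0.01, 0.1, 0.5)) {
    k <- rbinom(reps, n, p)
    low <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
    high <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
    # same quantities through the package, vectorized check on unique ks
    ci <- clopper_pearson(sort(unique(k)), n)
    expect_equal(ci$low, ifelse(sort(unique(k)) == 0, 0,
                                qbeta(0.025, sort(unique(k)),
                                      n - sort(unique(k)) + 1)))
    cover <- mean(low <= p & p <= high)
    expect_gte(cover, 0.94)
  }
})

test_that("BH adjustment is step-up, order-preserving and bounded", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(9)
  p <- runif(50)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted p
  expect_error(adjust_bh(numeric(0)), "empty")
})

test_that("Bonferroni threshold is alpha over the grid size", {
  expect_equal(bonferroni_threshold(0.05, 25, 10), 0.0002)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 7, 9) * 7 * 9, 0.05)
})

test_that("risk table covers the full cluster x outcome grid with joint BH", {
  cfg <- predo_default_config(seed = 31)
  co <- generate_cohort(cfg)
  tab <- compute_risk_table(co$truth, co$outcomes)
  K <- co$truth$K
  expect_identical(nrow(tab), K * 9L)
  expect_identical(anyDuplicated(tab[, c("cluster", "outcome")]), 0L)
  expect_true(all(tab$q_value >= tab$p_value - 1e-15))
  expect_true(all(tab$ci_low <= tab$rr & tab$rr <= tab$ci_high))
  expect_equal(tab$q_value, adjust_bh(tab$p_value))
  # BH never declares fewer discoveries than Bonferroni at the same alpha
  expect_gte(sum(tab$q_value < 0.05), sum(tab$significant_bonferroni))
  # zero-event cell contract
  zero <- tab[tab$k == 0, ][1, ]
  expect_equal(zero$rr, 0)
  expect_equal(zero$ci_low, 0)

  expect_error(compute_risk_table(partition(c(1, 2)), co$outcomes),
               "misaligned")
})

test_that("all-zero outcome column gives zero risk ratios everywhere", {
  co <- tiny_cohort()
  p <- partition(c(1, 1, 2))
  tab <- compute_risk_table(p, co$outcomes)
  expect_true(all(tab$rr[tab$outcome == "gh"] == 0))
})
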