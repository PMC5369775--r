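test_that("generator config validates weights, probabilities and rr bounds", {
  ref <- predo_reference_rates()
  rr <- matrix(1, 2, 8,
               dimnames = list(NULL, c("pe", "severe_pe", "early_pe",
                                       "intermediate_pe", "term_pe",
                                       "gh", "sga", "gdm")))
  proto <- matrix(0.5, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  ok <- generator_config(10, c(0.5, 0.5), proto, ref, rr, seed = 1)
  expect_s3_class(ok, "generator_config")

  expect_error(generator_config(10, c(0.6, 0.5), proto, ref, rr),
               "sum to 1")
  bad_rr <- rr; bad_rr[1, "pe"] <- 50  # 50 * 0.025 > 1
  expect_error(generator_config(10, c(0.5, 0.5), proto, ref, bad_rr),
               "exceeds 1")
  bad_p <- proto; bad_p[1, 1] <- 1.2
  expect_error(generator_config(10, c(0.5, 0.5), bad_p, ref, rr),
               "lie in \\[0,1\\]")
})

test_that("degenerate all-ones prototype yields an all-ones factor matrix", {
  ref <- predo_reference_rates()
  rr <- matrix(1, 1, 8,
               dimnames = list(NULL, c("pe", "severe_pe", "early_pe",
                                       "intermediate_pe", "term_pe",
                                       "gh", "sga", "gdm")))
  proto <- matrix(1, 1, 4, dimnames = list(NULL, paste0("f", 1:4)))
  cfg <- generator_config(10, 1, proto, ref, rr, seed = 2)
  co <- generate_cohort(cfg)
  expect_true(all(co$factors == 1L))
  expect_identical(co$truth$K, 1L)
})

test_that("generation is seed-deterministic and leaves the global RNG alone", {
  a <- generate_cohort(predo_default_config(seed = 5))
  b <- generate_cohort(predo_default_config(seed = 5))
  d <- generate_cohort(predo_default_config(seed = 6))
  expect_identical(unclass(a$factors), unclass(b$factors))
  expect_identical(unclass(a$outcomes), unclass(b$outcomes))
  expect_identical(a$truth$labels, b$truth$labels)
  expect_false(identical(unclass(a$factors), unclass(d$factors)))

  set.seed(77)
  before <- .Random.seed
  invisible(generate_cohort(predo_default_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("unit risk multipliers give pooled prevalence near the reference rate", {
  ref <- predo_reference_rates()
  rr <- matrix(1, 2, 8,
               dimnames = list(NULL, c("pe", "severe_pe", "early_pe",
                                       "intermediate_pe", "term_pe",
                                       "gh", "sga", "gdm")))
  proto <- matrix(c(0.8, 0.1), 2, 4)
  colnames(proto) <- paste0("f", 1:4)
  cfg <- generator_config(903, c(0.5, 0.5), proto, ref, rr, seed = 8)
  co <- generate_cohort(cfg)
  for (m in c("pe", "gh", "sga", "gdm")) {
    p0 <- ref[[m]]
    tol <- 3 * sqrt(p0 * (1 - p0) / 903)
    expect_lt(abs(mean(co$outcomes[, m]) - p0), tol,
              label = paste("pooled prevalence of", m))
  }
})

test_that("default study-like config matches the cohort's marginal structure", {
  cfg <- predo_default_config()
  w <- cfg$cluster_weights
  expect_equal(sum(w), 1, tolerance = 1e-9)
  marg <- colSums(w * cfg$prototype_matrix)
  expect_gte(marg[["bmi30"]], 0.35)
  expect_lte(marg[["bmi30"]], 0.43)
  expect_gt(marg[["pe_prev"]], 0.20)
  expect_lt(marg[["pe_prev"]], 0.30)
  pooled <- colSums(w * true_outcome_rates(cfg))
  expect_gte(pooled[["pe"]], 0.08)
  expect_lte(pooled[["pe"]], 0.11)
  # severity and early-onset shares at study-like magnitudes
  expect_gt(pooled[["severe_pe"]], 0.02)
  expect_lt(pooled[["severe_pe"]], 0.06)
  expect_gt(pooled[["early_pe"]], 0.005)
  expect_lt(pooled[["early_pe"]], 0.02)
})

test_that("generated cohorts always satisfy the outcome hierarchy", {
  for (seed in c(1, 12, 123)) {
    co <- generate_cohort(predo_default_config(seed = seed))
    expect_identical(nrow(validate_outcome_hierarchy(co$outcomes)), 0L)
  }
})

test_that("per-cluster factor frequencies converge to the prototypes", {
  ref <- predo_reference_rates()
  rr <- matrix(1, 2, 8,
               dimnames = list(NULL, c("pe", "severe_pe", "early_pe",
                                       "intermediate_pe", "term_pe",
                                       "gh", "sga", "gdm")))
  proto <- rbind(c(0.9, 0.3, 0.05), c(0.2, 0.7, 0.5))
  colnames(proto) <- paste0("f", 1:3)
  cfg <- generator_config(1000, c(0.5, 0.5), proto, ref, rr, seed = 99)
  co <- generate_cohort(cfg)
  for (c_ in 1:2) {
    g <- co$truth_clusters[c_]
    idx <- co$truth$labels == c_
    n_c <- sum(idx)
    expect_gte(n_c, 200)
    emp <- colMeans(co$factors[idx, , drop = FALSE])
    tol <- 3 * sqrt(proto[g, ] * (1 - proto[g, ]) / n_c)
    expect_true(all(abs(emp - proto[g, ]) <= tol),
                label = paste("cluster", c_, "frequencies within 3 SD"))
  }
})

test_that("risk-ratio estimation with the true partition covers the true values", {
  # over repeated cohorts the exact 95% CIs should contain the generating
  # risk ratio in >= 90% of (cluster, outcome) cells
  n_seeds <- 60
  hit <- 0L
  tot <- 0L
  for (seed in seq_len(n_seeds)) {
    cfg <- predo_default_config(seed = 1000 + seed)
    co <- generate_cohort(cfg)
    truth_p <- true_outcome_rates(cfg)
    p0 <- expand_subtype_rates(cfg$outcome_reference)
    tab <- compute_risk_table(co$truth, co$outcomes, cfg$outcome_reference)
    gen_row <- co$truth_clusters[tab$cluster]
    true_rr <- truth_p[cbind(gen_row, match(tab$outcome, colnames(truth_p)))] /
      p0[tab$outcome]
    hit <- hit + sum(tab$ci_low <= true_rr & true_rr <= tab$ci_high)
    tot <- tot + nrow(tab)
  }
  expect_gte(hit / tot, 0.90)
})
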