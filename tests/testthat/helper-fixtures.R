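# Shared fixture builders and independent oracles for the test suite.
# Oracles deliberately use a different computational route than the package
# (direct products of beta functions, explicit enumeration loops).

# small binary matrix with ids/names
bin_mat <- function(values, ids = NULL, names_ = NULL) {
  m <- matrix(values[[1]], nrow = length(values), byrow = TRUE,
              ncol = length(values[[1]]))
  for (i in seq_along(values)) m[i, ] <- values[[i]]
  rownames(m) <- ids %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- names_ %||% paste0("v", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent marginal-likelihood oracle: product over clusters and factors
# of B(a + k, b + n - k) / B(a, b) computed with base beta(), no logs until
# the end.
oracle_log_marginal <- function(X, labels, a = 1, b = 1) {
  tot <- 0
  for (c_ in unique(labels)) {
    sub <- X[labels == c_, , drop = FALSE]
    n <- nrow(sub)
    for (j in seq_len(ncol(sub))) {
      k <- sum(sub[, j])
      tot <- tot + log(beta(a + k, b + n - k) / beta(a, b))
    }
  }
  tot
}

# Exhaustive two-sided binomial p-value by explicit loop (minimum-likelihood
# convention, same tolerance as binom.test).
oracle_binom_p <- function(k, n, p0) {
  dk <- dbinom(k, n, p0)
  p <- 0
  for (i in 0:n) {
    di <- dbinom(i, n, p0)
    if (di <= dk * (1 + 1e-7)) p <- p + di
  }
  min(p, 1)
}

# Cohort with 4 well-separated prototypes (0.95 within two "hot" factors per
# cluster, 0.05 elsewhere), J = 8.
well_separated_cohort <- function(n = 400, seed = 1) {
  set.seed(seed)
  J <- 8
  proto <- matrix(0.05, 4, J)
  for (i in 1:4) proto[i, ((i - 1) * 2 + 1):(i * 2)] <- 0.95
  z <- sample(1:4, n, replace = TRUE)
  X <- matrix(rbinom(n * J, 1, proto[z, ]), n, J)
  colnames(X) <- paste0("f", 1:J)
  rownames(X) <- paste0("s", seq_len(n))
  list(X = X, z = z)
}

# Tiny valid cohort (3 subjects, 2 factors, full standard outcome set with a
# consistent hierarchy).
tiny_cohort <- function() {
  X <- bin_mat(list(c(1, 0), c(0, 1), c(1, 1)),
               names_ = c("pe_prev", "bmi30"))
  Y <- matrix(0L, 3, 9, dimnames = list(rownames(X), standard_outcomes()))
  Y[1, c("pe", "term_pe")] <- 1L
  list(factors = suppressWarnings(risk_factor_matrix(X)),
       outcomes = outcome_matrix(Y))
}
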