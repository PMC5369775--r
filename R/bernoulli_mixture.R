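# Collapsed Beta-Bernoulli mixture over partitions of binary risk-factor
# profiles. The per-cluster, per-factor Bernoulli parameters are integrated
# out under Beta(alpha0, beta0) priors, giving a closed-form marginal
# likelihood for any partition. The MAP partition under the chosen
# partition prior is found by stochastic greedy search over reassignment,
# merge and split moves, or by exhaustive enumeration at oracle scale.

#' Construct a partition of subjects into clusters
#'
#' @param labels integer vector of cluster labels; every label in
#'   `1:max(labels)` must be occupied (no empty clusters).
#' @return object of class `partition` with elements `labels` (canonical
#'   first-occurrence labelling) and `K`.
#' @export
partition <- function(labels) {
  labels <- as.integer(labels)
  if (!length(labels) || anyNA(labels) || any(labels < 1L))
    stop_("partition: labels must be positive integers")
  occupied <- sort(unique(labels))
  if (!identical(occupied, seq_len(max(labels))))
    stop_("partition: empty cluster label(s)")
  labels <- canonical_labels(labels)
  structure(list(labels = labels, K = max(labels)), class = "partition")
}

# Relabel clusters in order of first occurrence (the canonical labelling
# used for tie-breaking and determinism).
canonical_labels <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition of", length(x$labels), "subjects into", x$K, "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Beta-Bernoulli prior specification
#'
#' Three partition priors are available; all are truncated at
#' `max_clusters`.
#'
#' * `"ewens"` (default): the Ewens / Chinese-restaurant-process prior with
#'   concentration `theta`, whose log mass is, up to a constant,
#'   `K log(theta) + sum_c lgamma(n_c)`. It factorizes over clusters, never
#'   favours splitting identical profiles, and penalizes the spurious fine
#'   partitions that the marginal likelihood alone rewards on noisy binary
#'   data.
#' * `"uniform"`: flat over all partitions, so the MAP is the
#'   maximum-marginal-likelihood partition. On noisy data this
#'   systematically over-segments.
#' * `"uniform_k"`: uniform over the number of clusters K and then uniform
#'   over partitions with exactly K clusters (`-log S(n, K)`, Stirling
#'   numbers of the second kind). Note it concentrates prior mass on the
#'   near-singleton partitions at small n.
#'
#' @param alpha0 Beta pseudo-count for observed 1s (> 0).
#' @param beta0 Beta pseudo-count for observed 0s (> 0).
#' @param max_clusters cap on the number of clusters.
#' @param partition_prior `"ewens"`, `"uniform"` or `"uniform_k"`.
#' @param theta Ewens concentration parameter (> 0).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(alpha0 = 1, beta0 = 1, max_clusters = 30L,
                       partition_prior = c("ewens", "uniform", "uniform_k"),
                       theta = 1) {
  stopifnot(alpha0 > 0, beta0 > 0, max_clusters >= 1, theta > 0)
  structure(list(alpha0 = alpha0, beta0 = beta0,
                 max_clusters = as.integer(max_clusters),
                 partition_prior = match.arg(partition_prior),
                 theta = theta),
            class = "prior_spec")
}

# log Stirling numbers of the second kind, log S(n, k) for k = 1..kmax,
# by the stable log-space recurrence S(n,k) = k S(n-1,k) + S(n-1,k-1).
log_stirling2 <- function(n, kmax) {
  kmax <- min(kmax, n)
  ls <- rep(-Inf, kmax)
  ls[1L] <- 0  # S(1,1) = 1
  if (n == 1L) return(ls)
  for (i in 2:n) {
    new <- rep(-Inf, kmax)
    for (k in seq_len(min(i, kmax))) {
      a <- if (k <= length(ls)) log(k) + ls[k] else -Inf
      b <- if (k > 1L) ls[k - 1L] else -Inf
      m <- max(a, b)
      new[k] <- if (is.finite(m)) m + log(exp(a - m) + exp(b - m)) else -Inf
    }
    ls <- new
  }
  ls
}

#' Log prior of a partition (up to a constant)
#'
#' @param sizes integer vector of cluster sizes (all >= 1).
#' @param prior prior_spec.
#' @return log prior mass up to a partition-independent constant: 0 under
#'   the flat prior, `K log(theta) + sum lgamma(sizes)` under `"ewens"`,
#'   `-log S(n, K)` under `"uniform_k"`.
#' @export
log_partition_prior <- function(sizes, prior = prior_spec()) {
  K <- length(sizes)
  n <- sum(sizes)
  if (K > prior$max_clusters) return(-Inf)
  switch(prior$partition_prior,
         uniform = 0,
         ewens = K * log(prior$theta) + sum(lgamma(sizes)),
         uniform_k = -log_stirling2(n, min(prior$max_clusters, n))[K])
}

#' Search settings for the partition search
#'
#' @param n_restarts number of random restarts (>= 1).
#' @param max_sweeps maximum improvement sweeps per restart.
#' @param moves subset of `c("reassign", "merge", "split")`.
#' @param seed integer seed for the search's private RNG stream, or NULL.
#' @return object of class `search_settings`.
#' @export
search_settings <- function(n_restarts = 20L, max_sweeps = 50L,
                            moves = c("reassign", "merge", "split"),
                            seed = NULL) {
  stopifnot(n_restarts >= 1, max_sweeps >= 1,
            all(moves %in% c("reassign", "merge", "split")))
  structure(list(n_restarts = as.integer(n_restarts),
                 max_sweeps = as.integer(max_sweeps),
                 moves = moves, seed = seed),
            class = "search_settings")
}

# Score contribution of one cluster given its per-factor 1-counts k_j and
# size n: sum_j [ lbeta(a + k_j, b + n - k_j) - lbeta(a, b) ].
cluster_score <- function(kj, n, prior) {
  sum(lbeta(prior$alpha0 + kj, prior$beta0 + n - kj) -
        lbeta(prior$alpha0, prior$beta0))
}

# Per-cluster contribution to the MAP objective: collapsed likelihood plus
# the per-cluster factor of the Ewens prior (zero for the other priors,
# which enter through the K-indexed penalty instead).
cluster_obj <- function(kj, n, prior) {
  s <- cluster_score(kj, n, prior)
  if (prior$partition_prior == "ewens")
    s <- s + log(prior$theta) + lgamma(n)
  s
}

#' Log marginal likelihood of a partition
#'
#' Collapsed Beta-Bernoulli marginal: for each cluster c and factor j with
#' k_cj ones among n_c members,
#' `sum_cj log B(alpha0 + k_cj, beta0 + n_c - k_cj) / B(alpha0, beta0)`.
#' Invariant under relabelling of the clusters.
#'
#' @param factors risk_factor_matrix (or plain binary matrix).
#' @param partition `partition` object over the rows of `factors`.
#' @param prior prior_spec.
#' @return log marginal likelihood (finite real).
#' @export
log_marginal <- function(factors, partition, prior = prior_spec()) {
  stopifnot(inherits(partition, "partition"))
  if (length(partition$labels) != nrow(factors))
    stop_("log_marginal: partition length does not match the matrix")
  score <- 0
  for (c_ in seq_len(partition$K)) {
    idx <- partition$labels == c_
    score <- score +
      cluster_score(colSums(factors[idx, , drop = FALSE]), sum(idx), prior)
  }
  score
}

# All set partitions of n items as restricted growth strings, generated in
# lexicographic order (so the first maximum found is the canonically
# smallest labelling). Intended for n <= 10.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(m + 1L)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

#' Exhaustive MAP partition (oracle scale)
#'
#' Enumerates every set partition of the n subjects (Bell-number growth;
#' guarded at n <= 10), scores each with
#' `log_marginal + log_partition_prior`, and returns the maximizer with
#' K <= `max_clusters`. Ties break to the lexicographically smallest
#' canonical labelling.
#'
#' @inheritParams log_marginal
#' @return list with `partition`, `score` (the posterior objective) and
#'   `log_marginal`.
#' @export
enumerate_partitions_map <- function(factors, prior = prior_spec()) {
  n <- nrow(factors)
  if (n > 10L) stop_("enumerate_partitions_map: n > 10 (Bell-number guard)")
  best <- NULL
  best_score <- -Inf
  for (lab in all_partitions(n)) {
    if (max(lab) > prior$max_clusters) next
    p <- partition(lab)
    s <- log_marginal(factors, p, prior) +
      log_partition_prior(tabulate(p$labels), prior)
    if (s > best_score) {
      best_score <- s
      best <- p
    }
  }
  list(partition = best, score = best_score,
       log_marginal = log_marginal(factors, best, prior))
}

# --- greedy search over weighted unique profiles -------------------------

# Collapse duplicate rows: returns list(P = U x J unique-profile matrix,
# w = multiplicities, map = row -> profile index).
collapse_profiles <- function(factors) {
  key <- apply(factors, 1L, paste, collapse = "")
  u <- !duplicated(key)
  P <- unclass(factors)[u, , drop = FALSE]
  map <- match(key, key[u])
  list(P = P, w = as.integer(tabulate(map, nbins = sum(u))), map = map)
}

# Search state: z = profile labels (1..K), stats per cluster.
profile_state <- function(P, w, z) {
  K <- max(z)
  nj <- matrix(0, K, ncol(P))
  nc <- numeric(K)
  for (c_ in seq_len(K)) {
    idx <- z == c_
    nc[c_] <- sum(w[idx])
    nj[c_, ] <- colSums(P[idx, , drop = FALSE] * w[idx])
  }
  list(z = z, nc = nc, nj = nj)
}

state_score <- function(st, prior) {
  s <- 0
  for (c_ in seq_along(st$nc))
    s <- s + cluster_obj(st$nj[c_, ], st$nc[c_], prior)
  s
}

# One greedy pass of single-profile reassignments (to existing clusters or a
# new one). Mutates and returns (state, improved flag).
sweep_reassign <- function(st, P, w, prior, max_clusters, order, lp) {
  improved <- FALSE
  for (u in order) {
    c0 <- st$z[u]
    K <- length(st$nc)
    # contribution of source cluster with / without profile u
    s_c0 <- cluster_obj(st$nj[c0, ], st$nc[c0], prior)
    nj0 <- st$nj[c0, ] - w[u] * P[u, ]
    n0 <- st$nc[c0] - w[u]
    s_c0_out <- if (n0 > 0) cluster_obj(nj0, n0, prior) else 0
    best_delta <- 0
    best_d <- c0
    dK_empty <- if (n0 == 0) lp[K - 1L] - lp[K] else 0  # source would vanish
    targets <- setdiff(seq_len(K), c0)
    for (d in targets) {
      s_d <- cluster_obj(st$nj[d, ], st$nc[d], prior)
      s_d_in <- cluster_obj(st$nj[d, ] + w[u] * P[u, ], st$nc[d] + w[u], prior)
      delta <- (s_c0_out - s_c0) + (s_d_in - s_d) + dK_empty
      if (delta > best_delta + 1e-12) {
        best_delta <- delta
        best_d <- d
      }
    }
    # open a new cluster (only if source keeps members and cap allows)
    if (n0 > 0 && K < max_clusters) {
      s_new <- cluster_obj(w[u] * P[u, ], w[u], prior)
      delta <- (s_c0_out - s_c0) + s_new + (lp[K + 1L] - lp[K])
      if (delta > best_delta + 1e-12) {
        best_delta <- delta
        best_d <- K + 1L
      }
    }
    if (best_d != c0) {
      improved <- TRUE
      st$z[u] <- best_d
      st$nj[c0, ] <- nj0
      st$nc[c0] <- n0
      if (best_d > K) {
        st$nj <- rbind(st$nj, w[u] * P[u, ])
        st$nc <- c(st$nc, w[u])
      } else {
        st$nj[best_d, ] <- st$nj[best_d, ] + w[u] * P[u, ]
        st$nc[best_d] <- st$nc[best_d] + w[u]
      }
      if (st$nc[c0] == 0) {  # drop emptied cluster, relabel
        keep <- seq_along(st$nc) != c0
        st$nj <- st$nj[keep, , drop = FALSE]
        st$nc <- st$nc[keep]
        st$z <- st$z - (st$z > c0)
      }
    }
  }
  list(st = st, improved = improved)
}

# Best improving pairwise merge, applied repeatedly.
sweep_merge <- function(st, prior, lp) {
  improved <- FALSE
  repeat {
    K <- length(st$nc)
    if (K < 2L) break
    sc <- vapply(seq_len(K),
                 function(c_) cluster_obj(st$nj[c_, ], st$nc[c_], prior),
                 numeric(1))
    best_delta <- 0
    best_pair <- NULL
    for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
      s_ab <- cluster_obj(st$nj[a, ] + st$nj[b, ], st$nc[a] + st$nc[b], prior)
      delta <- s_ab - sc[a] - sc[b] + (lp[K - 1L] - lp[K])
      if (delta > best_delta + 1e-12) {
        best_delta <- delta
        best_pair <- c(a, b)
      }
    }
    if (is.null(best_pair)) break
    improved <- TRUE
    a <- best_pair[1L]; b <- best_pair[2L]
    st$nj[a, ] <- st$nj[a, ] + st$nj[b, ]
    st$nc[a] <- st$nc[a] + st$nc[b]
    st$z[st$z == b] <- a
    keep <- seq_along(st$nc) != b
    st$nj <- st$nj[keep, , drop = FALSE]
    st$nc <- st$nc[keep]
    st$z <- st$z - (st$z > b)
  }
  list(st = st, improved = improved)
}

# Split each multi-profile cluster by one step of 2-medoids on Hamming
# distance (medoids = the two most distant member profiles); apply the best
# improving split.
sweep_split <- function(st, P, w, prior, max_clusters, lp) {
  improved <- FALSE
  repeat {
    K <- length(st$nc)
    if (K >= max_clusters) break
    best_delta <- 0
    best_split <- NULL
    for (c_ in seq_len(K)) {
      members <- which(st$z == c_)
      if (length(members) < 2L) next
      Pm <- P[members, , drop = FALSE]
      D <- as.matrix(stats::dist(Pm, method = "manhattan"))
      far <- arrayInd(which.max(D), dim(D))
      m1 <- far[1L]; m2 <- far[2L]
      side2 <- D[, m2] < D[, m1]  # ties stay with the first medoid
      if (!any(side2) || all(side2)) next
      g1 <- members[!side2]; g2 <- members[side2]
      s_old <- cluster_obj(st$nj[c_, ], st$nc[c_], prior)
      nj1 <- colSums(P[g1, , drop = FALSE] * w[g1]); n1 <- sum(w[g1])
      nj2 <- colSums(P[g2, , drop = FALSE] * w[g2]); n2 <- sum(w[g2])
      delta <- cluster_obj(nj1, n1, prior) +
        cluster_obj(nj2, n2, prior) - s_old + (lp[K + 1L] - lp[K])
      if (delta > best_delta + 1e-12) {
        best_delta <- delta
        best_split <- list(c_ = c_, g2 = g2, nj1 = nj1, n1 = n1,
                           nj2 = nj2, n2 = n2)
      }
    }
    if (is.null(best_split)) break
    improved <- TRUE
    b <- best_split
    st$nj[b$c_, ] <- b$nj1
    st$nc[b$c_] <- b$n1
    st$nj <- rbind(st$nj, b$nj2)
    st$nc <- c(st$nc, b$n2)
    st$z[b$g2] <- length(st$nc)
  }
  list(st = st, improved = improved)
}

#' Search for the MAP partition
#'
#' Stochastic greedy search for the partition maximizing the collapsed
#' marginal likelihood. Duplicate risk-factor profiles are collapsed to
#' weighted unique profiles (exact for the marginal likelihood), so
#' identical profiles always share a cluster. Each restart starts from a
#' random partition of the profiles into K clusters (K drawn uniformly from
#' 2..max_clusters, capped at the number of unique profiles) and applies
#' greedy sweeps of single-profile reassignment, pairwise merge and
#' 2-medoids split moves until no move improves the score; the one-cluster
#' and all-singleton initializations are always included. The best partition
#' over all restarts is returned with canonical labelling.
#'
#' @inheritParams log_marginal
#' @param settings search_settings.
#' @return list with `partition` (over subjects), `score` (the posterior
#'   objective `log_marginal + log_partition_prior`), `log_marginal`, and
#'   `restart_scores` (best objective reached from each initialization).
#' @export
search_partition <- function(factors, prior = prior_spec(),
                             settings = search_settings()) {
  cp <- collapse_profiles(factors)
  U <- nrow(cp$P)
  n <- nrow(factors)
  kmax <- min(prior$max_clusters, U)
  # partition-prior penalty by K (over subjects, not collapsed profiles)
  lp <- if (prior$partition_prior == "uniform_k")
    -log_stirling2(n, min(prior$max_clusters, n))[seq_len(kmax)]
  else rep(0, kmax)
  run_from <- function(z0) {
    st <- profile_state(cp$P, cp$w, z0)
    for (s in seq_len(settings$max_sweeps)) {
      improved <- FALSE
      if ("reassign" %in% settings$moves) {
        r <- sweep_reassign(st, cp$P, cp$w, prior, kmax, sample.int(U), lp)
        st <- r$st; improved <- improved || r$improved
      }
      if ("merge" %in% settings$moves) {
        r <- sweep_merge(st, prior, lp)
        st <- r$st; improved <- improved || r$improved
      }
      if ("split" %in% settings$moves) {
        r <- sweep_split(st, cp$P, cp$w, prior, kmax, lp)
        st <- r$st; improved <- improved || r$improved
      }
      if (!improved) break
    }
    st
  }
  with_seed(settings$seed, {
    inits <- list(rep(1L, U))
    if (U > 1L && kmax > 1L)
      inits <- c(inits, list(canonical_labels(pmin(seq_len(U), kmax))))
    for (r in seq_len(settings$n_restarts)) {
      if (U == 1L || kmax == 1L) break
      K0 <- if (kmax == 2L) 2L else sample(2:kmax, 1L)
      z0 <- sample.int(K0, U, replace = TRUE)
      inits <- c(inits, list(canonical_labels(z0)))
    }
    best <- NULL
    best_score <- -Inf
    restart_scores <- numeric(length(inits))
    for (i in seq_along(inits)) {
      st <- run_from(inits[[i]])
      s <- state_score(st, prior) + lp[length(st$nc)]
      restart_scores[i] <- s
      if (s > best_score + 1e-12) {
        best_score <- s
        best <- st
      }
    }
    part <- partition(best$z[cp$map])
    list(partition = part,
         score = best_score,
         log_marginal = log_marginal(factors, part, prior),
         restart_scores = restart_scores)
  })
}
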