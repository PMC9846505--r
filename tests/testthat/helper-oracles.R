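# Independent reference implementations used as oracles. These are written
# in the most direct form possible (explicit loops, textbook formulas) and
# share no code with the package internals they check.

# Two-loop scaled dot-product attention
ref_attention <- function(Yp, W_K, W_Q, W_V) {
  K <- Yp %*% W_K; Q <- Yp %*% W_Q; V <- Yp %*% W_V
  n <- nrow(Yp); dk <- ncol(Yp)
  Z <- matrix(0, n, dk)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    r <- numeric(n)
    for (j in seq_len(n)) r[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(r - max(r)); w <- w / sum(w)
    W[i, ] <- w
    for (j in seq_len(n)) Z[i, ] <- Z[i, ] + w[j] * V[j, ]
  }
  list(Z = Z, weights = W)
}

# K-group log-rank chi-square via an explicit table over distinct event
# times (observed minus expected with hypergeometric variance).
ref_logrank_chi2 <- function(time, event, labels) {
  f <- factor(labels)
  K <- nlevels(f)
  groups <- levels(f)
  O <- E <- numeric(K)
  V <- matrix(0, K, K)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (k in seq_len(K)) {
      n_tk <- sum(at_risk & f == groups[k])
      d_tk <- sum(event == 1 & time == t & f == groups[k])
      O[k] <- O[k] + d_tk
      E[k] <- E[k] + d_t * n_tk / n_t
    }
    if (n_t > 1) {
      p <- vapply(groups, function(g) sum(at_risk & f == g) / n_t, numeric(1))
      V <- V + d_t * (n_t - d_t) / (n_t - 1) * (diag(p) - outer(p, p))
    }
  }
  u <- (O - E)[-K]
  drop(t(u) %*% solve(V[-K, -K, drop = FALSE], u))
}

# Pair-counting adjusted Rand index, O(n^2) over all sample pairs
ref_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  exp_idx <- (s11 + s10) * (s11 + s01) / choose(n, 2)
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Bayes-rule posterior for a 1-D Gaussian mixture evaluated directly
ref_gmm_posteriors <- function(z, pi_k, means, sds) {
  dens <- vapply(seq_along(pi_k),
                 function(k) pi_k[k] * dnorm(z, means[k], sds[k]),
                 numeric(length(z)))
  dens / rowSums(dens)
}

# Small multi-omics fixture shared across tests
tiny_dataset <- function(n = 24, widths = c(6, 5), seed = 11) {
  cfg <- simulation_config(n_samples = n, n_clusters = 2,
                           block_widths = widths, cluster_separation = 4,
                           informative_fraction = 0.5, seed = seed)
  simulate_multiomics(cfg)
}

tiny_arch <- function(widths = c(6, 5), d = 3, ...) {
  architecture_config(widths, d = d, ...)
}
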