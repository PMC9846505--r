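# log N(z | mu, Sigma) for all rows of Z, via the Cholesky factor of Sigma.
log_dmvnorm <- function(Z, mu, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) stop_numerical("singular component covariance despite ridge")
  d <- ncol(Z)
  xc <- sweep(Z, 2, mu)
  y <- backsolve(R, t(xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(y^2))
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(Z, K) {
  n <- nrow(Z)
  centers <- matrix(0, K, ncol(Z))
  centers[1, ] <- Z[sample.int(n, 1), ]
  d2 <- rowSums(sweep(Z, 2, centers[1, ])^2)
  if (K > 1) {
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- Z[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(Z, 2, centers[k, ])^2))
    }
  }
  centers
}

#' Fit a Gaussian mixture model by EM
#'
#' Models the integrated representation as
#' `p(z) = sum_k pi_k N(z | mu_k, Sigma_k)` with full component covariances,
#' regularized by adding `1e-6` to the diagonals. Component means are seeded
#' by k-means++; `n_init` restarts are run and the fit with the best final
#' log-likelihood is kept. EM stops when the log-likelihood gain falls below
#' `tol` or after `max_iter` iterations.
#'
#' @param Z numeric matrix, `N x d` (or a `latent_representation`).
#' @param K number of mixture components; must be `< N`.
#' @param n_init number of random restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood gain declaring convergence.
#' @param seed optional integer seed for the restarts.
#' @return An object of class `gmm_fit`: mixture weights `pi`, `means`
#'   (`K x d`), `covariances` (list of `d x d`), `responsibilities`
#'   (`N x K`), the per-iteration `loglik_trace` of the winning restart,
#'   `converged`, and `bic`.
#' @export
gmm_fit <- function(Z, K, n_init = 10, max_iter = 500, tol = 1e-4, seed = NULL) {
  if (inherits(Z, "latent_representation")) Z <- Z$Z
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (K >= n) stop_config("K (", K, ") must be smaller than the sample count (", n, ")")
  if (K < 1) stop_config("K must be >= 1")
  if (any(!is.finite(Z))) stop_data("Z contains non-finite values")
  ridge <- 1e-6
  with_seed(seed, {
    best <- NULL
    for (init in seq_len(n_init)) {
      fit <- em_run(Z, K, max_iter, tol, ridge)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    structure(list(K = K, pi = best$pi, means = best$means,
                   covariances = best$covariances,
                   responsibilities = best$resp,
                   loglik = best$loglik,
                   loglik_trace = best$trace,
                   converged = best$converged,
                   n_params = best$n_params,
                   bic = -2 * best$loglik + best$n_params * log(n)),
              class = "gmm_fit")
  })
}

# One EM run. Initialization: k-means++ seeds a k-means pass whose hard
# assignment provides the starting responsibilities (and hence the first
# M-step moments) — the same scheme scikit-learn's mixture models default to.
em_run <- function(Z, K, max_iter, tol, ridge) {
  n <- nrow(Z); d <- ncol(Z)
  centers <- kmeanspp_centers(Z, K)
  assign0 <- tryCatch(
    suppressWarnings(stats::kmeans(Z, centers = centers, iter.max = 100)$cluster),
    error = function(e) {
      d2 <- vapply(seq_len(K), function(k) rowSums(sweep(Z, 2, centers[k, ])^2),
                   numeric(n))
      max.col(-d2, ties.method = "first")
    })
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), assign0)] <- 1
  Nk <- pmax(colSums(resp), 1e-10)
  pi_k <- Nk / n
  means <- (t(resp) %*% Z) / Nk
  covariances <- lapply(seq_len(K), function(k) {
    xc <- sweep(Z, 2, means[k, ])
    crossprod(xc * sqrt(resp[, k])) / Nk[k] + diag(ridge, d)
  })
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## E-step in log space
    logdens <- vapply(seq_len(K), function(k) {
      log(pi_k[k]) + log_dmvnorm(Z, means[k, ], covariances[[k]])
    }, numeric(n))
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    resp <- exp(logdens - lse)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    ## M-step
    Nk <- colSums(resp)
    Nk <- pmax(Nk, 1e-10)
    pi_k <- Nk / n
    means <- (t(resp) %*% Z) / Nk
    covariances <- lapply(seq_len(K), function(k) {
      xc <- sweep(Z, 2, means[k, ])
      crossprod(xc * sqrt(resp[, k])) / Nk[k] + diag(ridge, d)
    })
  }
  n_params <- (K - 1) + K * d + K * d * (d + 1) / 2
  list(pi = pi_k, means = means, covariances = covariances, resp = resp,
       loglik = trace[length(trace)], trace = trace, converged = converged,
       n_params = n_params)
}

#' Assign samples to their maximum-posterior component
#'
#' Ties are broken toward the lowest component index.
#' @param fit a [gmm_fit()].
#' @param sample_ids optional identifiers.
#' @return A data.frame of class `cluster_assignment` with columns
#'   `sample_id`, `cluster`, `max_posterior`.
#' @export
gmm_assign <- function(fit, sample_ids = NULL) {
  stopifnot(inherits(fit, "gmm_fit"))
  resp <- fit$responsibilities
  labels <- max.col(resp, ties.method = "first")
  out <- data.frame(
    sample_id = sample_ids %||% sprintf("s%04d", seq_len(nrow(resp))),
    cluster = labels,
    max_posterior = resp[cbind(seq_len(nrow(resp)), labels)],
    stringsAsFactors = FALSE)
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions
#' (up to relabeling), about 0 for independent ones.
#' @param labels_a,labels_b label vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop_data("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n_pairs <- choose2(length(labels_a))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
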