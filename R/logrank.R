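prepare_survival <- function(time, event, labels) {
  if (length(time) != length(event) || length(time) != length(labels)) {
    stop_data("time, event and labels must have equal length")
  }
  keep <- !(is.na(time) | is.na(event) | is.na(labels))
  time <- time[keep]; event <- event[keep]; labels <- labels[keep]
  if (any(time < 0)) stop_data("survival times must be >= 0")
  if (!all(event %in% c(0, 1))) stop_data("event must be 0 or 1")
  f <- factor(labels)
  if (nlevels(f) < 2) stop_data("need at least 2 groups")
  if (sum(event) == 0) {
    stop_data("all observations censored; log-rank statistic undefined")
  }
  ord <- order(time)
  list(time = as.numeric(time[ord]), event = as.integer(event[ord]),
       labels = as.integer(f[ord]) - 1L, K = nlevels(f))
}

#' K-group log-rank test statistic
#'
#' The score (log-rank) chi-square of the Cox proportional-hazards model
#' with group indicators and no covariates: observed-minus-expected event
#' counts summed over distinct event times, with the hypergeometric
#' variance, on `K - 1` degrees of freedom.
#'
#' @param time nonnegative follow-up times.
#' @param event 0/1 event indicators (1 = death observed).
#' @param labels group labels (at least two non-empty groups).
#' @return List with `chi2`, `df`, and the asymptotic upper-tail
#'   `p_asymptotic`.
#' @export
logrank_statistic <- function(time, event, labels) {
  pr <- prepare_survival(time, event, labels)
  chi2 <- logrank_chi2_cpp(pr$time, pr$event, pr$labels, pr$K)
  df <- pr$K - 1L
  list(chi2 = chi2, df = df,
       p_asymptotic = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Initial permutation batch for the survival schedule:
# min(max(10 / p_asymptotic, 1e4), 1e6).
perm_initial_batch <- function(p_asymptotic) {
  min(max(ceiling(10 / max(p_asymptotic, 1e-300)), 1e4), 1e6)
}

# 95% binomial confidence interval for the permutation p-value. Wald around
# the (1+b)/(1+n) estimate, switching to Wilson on (b, n) when the expected
# success count is small.
perm_ci <- function(b, n_perm, p_hat, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (p_hat * n_perm < 5) {
    ph <- b / n_perm
    denom <- 1 + z^2 / n_perm
    centre <- (ph + z^2 / (2 * n_perm)) / denom
    half <- z * sqrt(ph * (1 - ph) / n_perm + z^2 / (4 * n_perm^2)) / denom
    lo <- centre - half; hi <- centre + half
  } else {
    half <- z * sqrt(p_hat * (1 - p_hat) / n_perm)
    lo <- p_hat - half; hi <- p_hat + half
  }
  c(max(0, min(lo, p_hat)), min(1, max(hi, p_hat)))
}

perm_result <- function(statistic, df, p_asymptotic, b, n_perm, stopped_by) {
  p_hat <- (1 + b) / (1 + n_perm)
  ci <- perm_ci(b, n_perm, p_hat)
  structure(list(p_hat = p_hat, ci_low = ci[1], ci_high = ci[2],
                 n_perm = n_perm, stopped_by = stopped_by,
                 statistic = statistic, df = df,
                 p_asymptotic = p_asymptotic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation p = %.4g (95%% CI %.4g-%.4g), %d permutations (%s)\n",
              x$p_hat, x$ci_low, x$ci_high, x$n_perm, x$stopped_by))
  cat(sprintf("observed statistic %.4g on %d df (asymptotic p = %.4g)\n",
              x$statistic, x$df, x$p_asymptotic))
  invisible(x)
}

# Stopping rule shared by the survival permutation schedule: both 95% CI
# ends within 10% of the estimate AND the interval clear of 0.05.
ci_condition_met <- function(p_hat, ci, alpha = 0.05) {
  within10 <- (ci[2] - p_hat) <= 0.1 * p_hat && (p_hat - ci[1]) <= 0.1 * p_hat
  clear <- ci[1] > alpha || ci[2] < alpha
  within10 && clear
}

#' Permutation-calibrated log-rank p-value
#'
#' Recomputes the log-rank chi-square under random relabelings of the
#' samples. The initial batch size is
#' `min(max(10 / p_asymptotic, 1e4), 1e6)` permutations; afterwards batches
#' of `1e5` are added until both ends of the 95% confidence interval lie
#' within 10% of the estimate and the interval is clear of 0.05, or until
#' `max_perm` permutations have been drawn. The p-value estimator is
#' `(1 + b) / (1 + n)` where `b` counts permuted statistics at least as
#' large as the observed one.
#'
#' @inheritParams logrank_statistic
#' @param seed optional integer seed; reruns with the same seed are
#'   identical.
#' @param max_perm permutation cap (default 1e6).
#' @param batch continuation batch size (default 1e5).
#' @return An object of class `permutation_result`: `p_hat`, `ci_low`,
#'   `ci_high`, `n_perm`, `stopped_by` (`ci_within_10pct`,
#'   `ci_clear_of_05` or `max_iterations`), the observed `statistic`, `df`
#'   and `p_asymptotic`.
#' @export
permutation_pvalue_logrank <- function(time, event, labels, seed = NULL,
                                       max_perm = 1e6, batch = 1e5) {
  pr <- prepare_survival(time, event, labels)
  chi2 <- logrank_chi2_cpp(pr$time, pr$event, pr$labels, pr$K)
  df <- pr$K - 1L
  p_asym <- stats::pchisq(chi2, df, lower.tail = FALSE)
  b0 <- min(perm_initial_batch(p_asym), max_perm)
  with_seed(seed, {
    tol <- 1e-12
    stats_perm <- logrank_perm_cpp(pr$time, pr$event, pr$labels, pr$K, as.integer(b0))
    b <- sum(stats_perm >= chi2 - tol)
    n_perm <- b0
    repeat {
      p_hat <- (1 + b) / (1 + n_perm)
      ci <- perm_ci(b, n_perm, p_hat)
      if (ci_condition_met(p_hat, ci)) {
        return(perm_result(chi2, df, p_asym, b, n_perm, "ci_within_10pct"))
      }
      if (n_perm >= max_perm) {
        return(perm_result(chi2, df, p_asym, b, n_perm, "max_iterations"))
      }
      nb <- as.integer(min(batch, max_perm - n_perm))
      extra <- logrank_perm_cpp(pr$time, pr$event, pr$labels, pr$K, nb)
      b <- b + sum(extra >= chi2 - tol)
      n_perm <- n_perm + nb
    }
  })
}
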