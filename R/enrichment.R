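#' Kruskal-Wallis test of a numeric clinical label across clusters
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' `K - 1` degrees of freedom. Missing values are dropped pairwise. If all
#' remaining values are tied the test is degenerate and `H = 0`, `p = 1`
#' is returned.
#'
#' @param values numeric vector.
#' @param labels group labels.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, labels) {
  keep <- !(is.na(values) | is.na(labels))
  values <- values[keep]; labels <- factor(labels[keep])
  if (nlevels(droplevels(labels)) < 2) stop_data("need at least 2 groups")
  labels <- droplevels(labels)
  if (length(unique(values)) < 2) {
    return(list(H = 0, df = nlevels(labels) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Pearson chi-square test of a categorical clinical label across clusters
#'
#' No continuity correction; `df = (r - 1)(c - 1)`. Missing values are
#' dropped pairwise; a degenerate table (fewer than two non-empty rows or
#' columns) is an error.
#'
#' @param categories categorical vector.
#' @param labels group labels.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_enrichment <- function(categories, labels) {
  keep <- !(is.na(categories) | is.na(labels))
  tab <- table(droplevels(factor(categories[keep])),
               droplevels(factor(labels[keep])))
  if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_data("degenerate contingency table for chi-square test")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

# Vectorized permuted statistics. Permuting cluster labels is equivalent to
# permuting the covariate; `idx` is an n x B matrix of permuted sample
# indices and group sizes stay fixed, so grouped sums via rowsum() give all
# B statistics in a handful of calls.
perm_stats_kruskal <- function(r, labels, tie_corr, idx) {
  n <- length(r)
  Rp <- matrix(r[idx], n, ncol(idx))
  S <- rowsum(Rp, labels)
  nk <- as.vector(table(labels))
  H <- 12 / (n * (n + 1)) * colSums(S^2 / nk) - 3 * (n + 1)
  H / tie_corr
}

perm_stats_chisq <- function(categories, labels, idx) {
  n <- length(categories)
  lev <- levels(categories)
  tab <- table(categories, labels)
  Eexp <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- numeric(ncol(idx))
  for (a in seq_along(lev)) {
    Cp <- matrix(categories[idx] == lev[a], n, ncol(idx))
    O <- rowsum(Cp + 0, labels)            # K x B counts for category a
    chi2 <- chi2 + colSums((O - Eexp[a, ])^2 / Eexp[a, ])
  }
  chi2
}

#' Permutation-calibrated p-value for a clinical-enrichment statistic
#'
#' Adds batches of `1e3` label permutations until the 95% confidence
#' interval for the p-value no longer crosses 0.05, up to `max_perm`
#' (default `1e5`) permutations. Larger permuted statistics count against
#' the null (right tail).
#'
#' @param test `"kruskal"`, `"chisq"`, or a function `f(data, labels)`
#'   returning a scalar statistic.
#' @param data the clinical covariate (numeric for Kruskal-Wallis,
#'   categorical for chi-square).
#' @param labels cluster labels.
#' @param seed optional integer seed.
#' @param batch permutations per batch.
#' @param max_perm permutation cap.
#' @return An object of class `permutation_result`.
#' @export
permutation_pvalue_enrichment <- function(test, data, labels, seed = NULL,
                                          batch = 1e3, max_perm = 1e5) {
  keep <- !(is.na(data) | is.na(labels))
  data <- data[keep]; labels <- labels[keep]
  n <- length(data)
  if (is.function(test)) {
    obs <- test(data, labels)
    df <- NA_integer_
    p_asym <- NA_real_
    gen <- function(B) {
      vapply(seq_len(B), function(b) test(data[sample.int(n)], labels), numeric(1))
    }
  } else if (identical(test, "kruskal")) {
    kw <- kruskal_wallis(data, labels)
    obs <- kw$H; df <- kw$df; p_asym <- kw$p
    labf <- droplevels(factor(labels))
    r <- rank(data)
    ties <- table(r)
    tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (tie_corr <= 0) tie_corr <- 1
    gen <- function(B) {
      idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
      perm_stats_kruskal(r, labf, tie_corr, idx)
    }
  } else if (identical(test, "chisq")) {
    cs <- chi_square_enrichment(data, labels)
    obs <- cs$chi2; df <- cs$df; p_asym <- cs$p
    catf <- droplevels(factor(data))
    labf <- droplevels(factor(labels))
    gen <- function(B) {
      idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
      perm_stats_chisq(catf, labf, idx)
    }
  } else {
    stop_config("unknown test: ", test)
  }
  with_seed(seed, {
    tol <- 1e-12
    b <- 0; n_perm <- 0
    repeat {
      nb <- as.integer(min(batch, max_perm - n_perm))
      b <- b + sum(gen(nb) >= obs - tol)
      n_perm <- n_perm + nb
      p_hat <- (1 + b) / (1 + n_perm)
      ci <- perm_ci(b, n_perm, p_hat)
      if (ci[1] > 0.05 || ci[2] < 0.05) {
        return(perm_result(obs, df, p_asym, b, n_perm, "ci_clear_of_05"))
      }
      if (n_perm >= max_perm) {
        return(perm_result(obs, df, p_asym, b, n_perm, "max_iterations"))
      }
    }
  })
}

#' Clinical-enrichment analysis of a subtype assignment
#'
#' Tests each clinical label column against the cluster labels: numeric
#' labels with the Kruskal-Wallis test (asymptotic p), categorical labels
#' with the Pearson chi-square test calibrated by label permutation. Labels
#' with a single observed level are skipped with a warning. The headline
#' number is the count of labels significant at `alpha`.
#'
#' @param clinical a [clinical_table()] (columns beyond `sample_id`, `time`,
#'   `event` are the labels) or a plain data.frame of label columns.
#' @param labels cluster labels, aligned with the clinical rows.
#' @param alpha significance threshold (default 0.05).
#' @param seed optional integer seed for the permutation calibration.
#' @return An object of class `enrichment_report`: per-label test results
#'   and `n_significant`.
#' @export
enrichment_count <- function(clinical, labels, alpha = 0.05, seed = NULL) {
  cols <- setdiff(colnames(clinical), c("sample_id", "time", "event"))
  if (length(cols) == 0) stop_data("no clinical label columns present")
  results <- list()
  seed_i <- seed
  for (cn in cols) {
    v <- clinical[[cn]]
    keep <- !is.na(v)
    if (length(unique(v[keep])) < 2) {
      warning("clinical label '", cn, "' has a single level; skipped")
      next
    }
    entry <- if (is.numeric(v)) {
      kw <- kruskal_wallis(v, labels)
      list(label = cn, test = "kruskal_wallis", statistic = kw$H,
           p = kw$p, perm = NULL)
    } else {
      res <- tryCatch(
        permutation_pvalue_enrichment("chisq", v, labels, seed = seed_i),
        sadln_data_error = function(e) NULL)
      if (is.null(res)) {
        warning("clinical label '", cn, "' gives a degenerate table; skipped")
        NULL
      } else {
        list(label = cn, test = "chi_square", statistic = res$statistic,
             p = res$p_hat, perm = res)
      }
    }
    if (!is.null(seed_i)) seed_i <- seed_i + 1
    if (!is.null(entry)) results[[cn]] <- entry
  }
  ps <- vapply(results, function(r) r$p, numeric(1))
  structure(list(results = results, alpha = alpha,
                 n_tested = length(results),
                 n_significant = sum(ps < alpha)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("clinical enrichment:", x$n_significant, "of", x$n_tested,
      "labels significant at alpha =", x$alpha, "\n")
  for (r in x$results) {
    cat(sprintf("  %-16s %-14s p = %.4g\n", r$label, r$test, r$p))
  }
  invisible(x)
}
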