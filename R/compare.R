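#' Friedman rank test across methods and datasets
#'
#' Ranks methods within each dataset (average ranks on ties) and tests
#' whether mean ranks differ, with a chi-square on `methods - 1` degrees of
#' freedom. Used to compare subtyping algorithms over a panel of cancer
#' datasets.
#'
#' @param score_matrix numeric matrix, datasets in rows, methods in columns;
#'   no missing cells.
#' @return List with `chi2`, `df`, `p` and `mean_ranks` (higher score =
#'   higher rank).
#' @export
friedman_compare <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) stop_data("need at least 2 datasets and 2 methods")
  if (anyNA(m)) stop_data("score matrix has missing cells")
  ranks <- t(apply(m, 1, rank))
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    # every dataset ranks all methods equally: no evidence of differences
    return(list(chi2 = 0, df = ncol(m) - 1L, p = 1,
                mean_ranks = stats::setNames(colMeans(ranks), colnames(m))))
  }
  ft <- stats::friedman.test(m)
  list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
       p = unname(ft$p.value),
       mean_ranks = stats::setNames(colMeans(ranks), colnames(m)))
}

#' Kaplan-Meier survival curves per cluster
#'
#' Product-limit estimates for each group; every curve starts at
#' `(time = 0, survival = 1)` and is non-increasing.
#'
#' @inheritParams logrank_statistic
#' @return A data.frame with columns `group`, `time`, `survival`, `n_risk`,
#'   `n_event`.
#' @export
km_estimate <- function(time, event, labels) {
  keep <- !(is.na(time) | is.na(event) | is.na(labels))
  time <- time[keep]; event <- event[keep]
  g <- droplevels(factor(labels[keep]))
  if (any(table(g) == 0) || nlevels(g) < 1) stop_data("empty group")
  out <- lapply(levels(g), function(lv) {
    sel <- g == lv
    fit <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    data.frame(group = lv,
               time = c(0, fit$time),
               survival = c(1, fit$surv),
               n_risk = c(sum(sel), fit$n.risk),
               n_event = c(0, fit$n.event),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
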