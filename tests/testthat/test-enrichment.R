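test_that("Kruskal-Wallis reproduces the tie-free hand example", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$H, 3.857143, tolerance = 1e-6)
  expect_equal(r$df, 1)
  # invariant under strictly monotone transforms of the values
  r2 <- kruskal_wallis(exp(c(1, 2, 3, 4, 5, 6)), rep(c("a", "b"), each = 3))
  expect_equal(r2$H, r$H, tolerance = 1e-12)
})

test_that("degenerate Kruskal-Wallis inputs behave as documented", {
  r <- kruskal_wallis(rep(2, 8), rep(1:2, each = 4))
  expect_equal(r$H, 0)
  expect_equal(r$p, 1)
  expect_error(kruskal_wallis(1:4, rep(1, 4)), class = "sadln_data_error")
  # missing values dropped pairwise
  r2 <- kruskal_wallis(c(1, 2, 3, NA, 4, 5, 6, NA),
                       rep(c("a", "b"), each = 4))
  expect_equal(r2$H, 3.857143, tolerance = 1e-6)
})

test_that("chi-square enrichment matches closed forms", {
  balanced <- list(cat = rep(c("x", "y"), each = 20),
                   lab = rep(rep(1:2, each = 10), 2))
  r <- chi_square_enrichment(balanced$cat, balanced$lab)
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  diagonal <- list(cat = rep(c("x", "y"), each = 20),
                   lab = rep(1:2, each = 20))
  r2 <- chi_square_enrichment(diagonal$cat, diagonal$lab)
  expect_equal(r2$chi2, 40, tolerance = 1e-12)
  expect_equal(r2$df, 1)
  # swapping category rows changes nothing
  r3 <- chi_square_enrichment(rev(diagonal$cat), rev(diagonal$lab))
  expect_equal(r3$chi2, 40, tolerance = 1e-12)
  expect_error(chi_square_enrichment(rep("x", 10), rep(1:2, 5)),
               class = "sadln_data_error")
})

test_that("a strong association stops the enrichment permutations after one batch", {
  cat <- rep(c("x", "y"), each = 20)
  lab <- rep(1:2, each = 20)
  r <- permutation_pvalue_enrichment("chisq", cat, lab, seed = 5)
  expect_equal(r$n_perm, 1e3)
  expect_equal(r$stopped_by, "ci_clear_of_05")
  expect_lt(r$p_hat, 0.01)
})

test_that("enrichment permutations are seeded and capped", {
  set.seed(17)
  v <- rnorm(60)
  lab <- rep(1:3, 20)
  a <- permutation_pvalue_enrichment("kruskal", v, lab, seed = 6)
  b <- permutation_pvalue_enrichment("kruskal", v, lab, seed = 6)
  expect_identical(a$p_hat, b$p_hat)
  expect_identical(a$n_perm, b$n_perm)
  expect_lte(a$n_perm, 1e5)
  expect_true(a$stopped_by %in% c("ci_clear_of_05", "max_iterations"))
})

test_that("vectorized permutation statistics match the direct statistic path", {
  set.seed(18)
  v <- c(rnorm(30), rnorm(30, 0.5))
  lab <- rep(1:2, each = 30)
  fast <- permutation_pvalue_enrichment("kruskal", v, lab, seed = 9,
                                        batch = 200, max_perm = 200)
  slow <- permutation_pvalue_enrichment(function(d, l) kruskal_wallis(d, l)$H,
                                        v, lab, seed = 9,
                                        batch = 200, max_perm = 200)
  expect_equal(fast$p_hat, slow$p_hat, tolerance = 1e-12)

  cat <- sample(c("x", "y", "z"), 60, replace = TRUE)
  fastc <- permutation_pvalue_enrichment("chisq", cat, lab, seed = 10,
                                         batch = 200, max_perm = 200)
  slowc <- permutation_pvalue_enrichment(function(d, l) chi_square_enrichment(d, l)$chi2,
                                         cat, lab, seed = 10,
                                         batch = 200, max_perm = 200)
  expect_equal(fastc$p_hat, slowc$p_hat, tolerance = 1e-12)
})

test_that("enrichment counting finds linked labels and skips degenerate ones", {
  set.seed(19)
  n <- 120
  clusters <- rep(1:3, each = 40)
  clinical <- clinical_table(
    sprintf("s%03d", 1:n), rexp(n), rbinom(n, 1, 0.7),
    labels = data.frame(
      linked_num = clusters * 2 + rnorm(n, sd = 0.5),
      noise_num = rnorm(n),
      constant = rep("same", n),
      noise_cat = sample(c("p", "q"), n, replace = TRUE),
      stringsAsFactors = FALSE))
  expect_warning(rep_ <- enrichment_count(clinical, clusters, seed = 11),
                 "single level")
  expect_gte(rep_$n_significant, 1)
  expect_lte(rep_$n_significant, rep_$n_tested)
  expect_equal(rep_$n_tested, 3)  # constant column skipped
  expect_lt(rep_$results$linked_num$p, 0.05)
})

test_that("unlinked labels yield a zero enrichment count", {
  set.seed(20)
  n <- 90
  clusters <- rep(1:3, each = 30)
  clinical <- clinical_table(
    sprintf("s%03d", 1:n), rexp(n), rbinom(n, 1, 0.7),
    labels = data.frame(noise = rnorm(n),
                        cat = sample(c("p", "q"), n, replace = TRUE)))
  rep_ <- enrichment_count(clinical, clusters, seed = 12)
  expect_equal(rep_$n_significant, 0)
})
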