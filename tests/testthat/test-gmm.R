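test_that("a single component recovers the data's own moments", {
  set.seed(5)
  Z <- matrix(rnorm(200), 50, 4)
  fit <- gmm_fit(Z, 1, n_init = 1, seed = 1)
  expect_equal(fit$pi, 1)
  expect_equal(drop(fit$means), colMeans(Z), tolerance = 1e-8)
  mle_cov <- crossprod(sweep(Z, 2, colMeans(Z))) / 50
  expect_equal(fit$covariances[[1]], mle_cov + diag(1e-6, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("two well-separated 1-D components are recovered", {
  set.seed(6)
  z <- matrix(c(rnorm(100, -5, 0.5), rnorm(100, 5, 0.5)))
  truth <- rep(1:2, each = 100)
  fit <- gmm_fit(z, 2, n_init = 5, seed = 2)
  expect_equal(sort(drop(fit$means)), c(-5, 5), tolerance = 0.2)
  expect_equal(ari(gmm_assign(fit)$cluster, truth), 1)
})

test_that("responsibilities equal the brute-force Bayes posterior", {
  z <- matrix(c(-1, 0, 2))
  fit <- gmm_fit(z, 2, n_init = 4, max_iter = 100, seed = 3)
  sds <- sqrt(vapply(fit$covariances, function(s) s[1, 1], numeric(1)))
  want <- ref_gmm_posteriors(drop(z), fit$pi, drop(fit$means), sds)
  expect_equal(unname(fit$responsibilities), unname(want), tolerance = 1e-10)
  expect_equal(rowSums(fit$responsibilities), rep(1, 3), tolerance = 1e-12)
})

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  set.seed(9)
  for (rep in 1:5) {
    Z <- rbind(matrix(rnorm(60, -1), 30, 2), matrix(rnorm(60, 1), 30, 2))
    fit <- gmm_fit(Z, sample(2:3, 1), n_init = 2, seed = rep)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("fits are deterministic given a seed and reject bad K", {
  set.seed(10)
  Z <- matrix(rnorm(80), 40, 2)
  a <- gmm_fit(Z, 2, n_init = 3, seed = 4)
  b <- gmm_fit(Z, 2, n_init = 3, seed = 4)
  expect_identical(a$responsibilities, b$responsibilities)
  expect_identical(a$loglik, b$loglik)
  expect_error(gmm_fit(Z, 40, seed = 1), class = "sadln_config_error")
  expect_error(gmm_fit(Z, 0, seed = 1), class = "sadln_config_error")
})

test_that("estimated means land within three standard errors of truth", {
  set.seed(11)
  n_per <- 150
  mu_true <- c(-6, 0, 6)
  Z <- cbind(c(rnorm(n_per, -6, 1), rnorm(n_per, 0, 1), rnorm(n_per, 6, 1)))
  fit <- gmm_fit(Z, 3, n_init = 5, seed = 6)
  se <- 1 / sqrt(n_per)
  expect_true(all(abs(sort(drop(fit$means)) - mu_true) < 3 * se))
})

test_that("assignment takes the maximum posterior with ties to the lower index", {
  fit <- structure(list(K = 2,
                        responsibilities = rbind(c(0.9, 0.1), c(0.5, 0.5),
                                                 c(0.2, 0.8))),
                   class = "gmm_fit")
  asg <- gmm_assign(fit, c("a", "b", "c"))
  expect_equal(asg$cluster, c(1, 1, 2))
  expect_equal(asg$max_posterior, c(0.9, 0.5, 0.8))
})

test_that("cluster agreement matches mclust's on a trained fit", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(12)
  Z <- rbind(matrix(rnorm(100, -2, .6), 50, 2), matrix(rnorm(100, 2, .6), 50, 2))
  fit <- gmm_fit(Z, 2, n_init = 5, seed = 7)
  mc <- mclust::Mclust(Z, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(ari(gmm_assign(fit)$cluster, mc$classification), 1)
})

test_that("adjusted Rand index follows the pair-counting definition", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # relabeling invariance
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(13)
  for (i in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(ari(a, b), ref_ari(a, b), tolerance = 1e-12)
  }
  expect_error(ari(1:3, 1:4), class = "sadln_data_error")
})
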