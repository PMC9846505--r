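test_that("sub-network forward is the stated affine map", {
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(sub_network_forward(x, diag(4), rep(0, 4)), x)
  # (a, b) -> a + b with bias 1
  expect_equal(sub_network_forward(matrix(c(1, 2), 1), matrix(c(1, 1), 2, 1), 1),
               matrix(4, 1, 1))
  b <- c(2, -1)
  out <- sub_network_forward(matrix(0, 3, 2), matrix(0, 2, 2), b)
  expect_equal(out, matrix(b, 3, 2, byrow = TRUE))
  expect_error(sub_network_forward(x, diag(3), rep(0, 3)), class = "sadln_data_error")
})

test_that("concatenation preserves block order and widths", {
  y1 <- matrix(1, 3, 2); y2 <- matrix(2, 3, 4)
  out <- concat_features(list(y1, y2))
  expect_equal(dim(out), c(3, 6))
  expect_equal(out[, 1:2], y1)
  expect_equal(out[, 3:6], y2)
  expect_equal(concat_features(list(y1)), y1)
  expect_error(concat_features(list(y1, matrix(1, 2, 2))), class = "sadln_data_error")
})

test_that("default four-block architecture yields a 100-dimensional representation", {
  cfg <- architecture_config(c(40, 40, 20, 40), epochs = 0)
  model <- sadln_init(cfg)
  sim <- simulate_multiomics(simulation_config(
    n_samples = 30, block_widths = c(40, 40, 20, 40), seed = 4))
  lat <- encode(model, sim$data)
  expect_equal(ncol(lat$Z), 100)
  expect_equal(lat$Z, lat$mu)
})

test_that("inference-mode encoding is a pure function", {
  sim <- tiny_dataset()
  model <- sadln_init(tiny_arch())
  a <- encode(model, sim$data)
  b <- encode(model, sim$data)
  expect_identical(a$Z, b$Z)
})

test_that("without attention the encoder is sample-wise equivariant; with attention it is not", {
  sim <- tiny_dataset()
  n <- length(sim$data$sample_ids)
  set.seed(8)
  perm <- sample(n)
  permute <- function(ds, idx) {
    omics_dataset(lapply(ds$blocks, function(b) {
      omics_block(b$name, b$values[idx, , drop = FALSE], b$feature_ids)
    }), ds$sample_ids[idx])
  }
  m_plain <- sadln_init(tiny_arch(use_attention = FALSE))
  z1 <- encode(m_plain, sim$data)$Z
  z2 <- encode(m_plain, permute(sim$data, perm))$Z
  expect_equal(z2, z1[perm, ], tolerance = 1e-12)

  # with attention, dropping co-batched samples changes a retained sample's code
  m_att <- sadln_init(tiny_arch())
  full <- encode(m_att, sim$data)$Z
  subset_idx <- 1:10
  sub <- encode(m_att, permute(sim$data, subset_idx))$Z
  expect_gt(max(abs(sub - full[subset_idx, ])), 1e-8)
})

test_that("decoder reconstructions have the input blocks' shapes", {
  cfg <- tiny_arch()
  model <- sadln_init(cfg)
  Z <- matrix(rnorm(8 * cfg$latent_dim), 8)
  outs <- decode(model, Z)
  expect_length(outs, 2)
  expect_equal(vapply(outs, dim, integer(2)), cbind(c(8, 6), c(8, 5)))
  # zeroed output heads with bias c give a constant reconstruction
  model$params$head1.W[] <- 0
  model$params$head1.b[] <- 7
  outs <- decode(model, Z)
  expect_true(all(outs[[1]] == 7))
})

test_that("layer accounting matches the printed architecture", {
  cfg <- architecture_config(c(40, 40, 20, 40), epochs = 0)
  s <- model_summary(sadln_init(cfg))
  expect_equal(unname(s$counts), c(10, 5, 4, 19))
  expect_gt(s$n_parameters, 0)
  s2 <- model_summary(sadln_init(architecture_config(c(40, 40, 20, 40),
                                                     use_attention = FALSE)))
  expect_equal(unname(s2$counts["encoder"]), 9)
  expect_equal(unname(s2$counts["total"]), 18)
})

test_that("checkpoints reload with bit-identical inference", {
  sim <- tiny_dataset()
  tr <- sadln_train(zscore_blocks(sim$data), tiny_arch(epochs = 3, batch_size = 12))
  path <- withr::local_tempfile(fileext = ".rds")
  sadln_save(tr$model, path)
  back <- sadln_load(path)
  expect_identical(encode(back, sim$data)$Z, encode(tr$model, sim$data)$Z)
})

test_that("backpropagated gradients match finite differences", {
  sim <- tiny_dataset(n = 12)
  dz <- zscore_blocks(sim$data)
  Xs <- lapply(dz$blocks, function(b) b$values)
  cfg <- tiny_arch()
  model <- sadln_init(cfg)
  eps0 <- matrix(0, 12, cfg$latent_dim)  # deterministic latent draw

  loss_fn <- function(m) {
    ef <- sadln:::encoder_forward(m, Xs, training = TRUE, eps = eps0)
    df <- sadln:::decoder_forward(m, ef$Z, training = TRUE)
    decoder_loss(Xs, df$outs)
  }
  ef <- sadln:::encoder_forward(model, Xs, training = TRUE, eps = eps0)
  df <- sadln:::decoder_forward(model, ef$Z, training = TRUE)
  nb <- 12; M <- 2
  dOuts <- lapply(seq_len(M), function(m) 2 * (df$outs[[m]] - Xs[[m]]) / (M * nb))
  db <- sadln:::decoder_backward(model, df$cache, dOuts)
  ge <- sadln:::encoder_backward(model, ef$cache, db$dZ)
  grads <- c(ge, db$grads)

  h <- 1e-5
  for (nm in c("sub1.W", "att.WQ", "fc.W", "mu.W", "dec.W", "head2.W", "bn1.gamma")) {
    i <- 2  # a fixed entry of each tensor
    mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
    mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
    fd <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
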