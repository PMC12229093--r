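# Stage-2 decoder: projection, transformer decoding, MSE, and the
# frozen-encoder training contract.

test_that("projection meets shape, zero and linearity contracts", {
  dec <- expression_decoder(tiny_decoder_config(in_dim = 16L,
                                                n_genes_out = 10L),
                            seed = 2L)
  V <- matrix(rnorm(4 * 16), 4, 16)
  Ep <- project_features(dec, V)
  expect_equal(dim(Ep), c(4, 64))
  # zero input with zero biases -> zero output
  dz <- dec
  dz$params$proj1$b[] <- 0
  dz$params$proj2$b[] <- 0
  expect_equal(project_features(dz, matrix(0, 2, 16)), matrix(0, 2, 64))
  # with the nonlinearity disabled the map is affine: constant Jacobian
  dl <- dec
  dl$config$proj_nonlinear <- FALSE
  f <- function(v) project_features(dl, matrix(v, 1))[1, ]
  v0 <- rnorm(16)
  j1 <- vapply(1:16, function(i) {
    e <- rep(0, 16); e[i] <- 1e-4
    (f(v0 + e) - f(v0 - e)) / 2e-4
  }, numeric(64))
  v1 <- rnorm(16)
  j2 <- vapply(1:16, function(i) {
    e <- rep(0, 16); e[i] <- 1e-4
    (f(v1 + e) - f(v1 - e)) / 2e-4
  }, numeric(64))
  expect_equal(j1, j2, tolerance = 1e-6)
})

test_that("multi-head decoding matches the brute-force oracle and a
           one-head concat is a single head", {
  set.seed(81)
  p <- histex:::init_mha(8L, 8L, 8L, 1L)
  x <- matrix(rnorm(32), 4, 8)
  tp <- histex:::tape_new()
  pn <- histex:::tree_nodes(tp, p, FALSE)
  one <- histex:::nn_mha(tp, histex:::ad_const(tp, x),
                         histex:::ad_const(tp, x), pn, 1L)$v
  expect_equal(one, naive_mha(x, x, p, 1L), tolerance = 1e-10)
  p2 <- histex:::init_mha(8L, 8L, 8L, 2L)
  tp2 <- histex:::tape_new()
  two <- histex:::nn_mha(tp2, histex:::ad_const(tp2, x),
                         histex:::ad_const(tp2, x),
                         histex:::tree_nodes(tp2, p2, FALSE), 2L)$v
  expect_equal(two, naive_mha(x, x, p2, 2L), tolerance = 1e-10)
  # output head emits one value per target gene
  dec <- expression_decoder(tiny_decoder_config(in_dim = 16L,
                                                n_genes_out = 37L),
                            seed = 3L)
  Xp <- predict_expression(dec, matrix(rnorm(3 * 16), 3, 16))
  expect_equal(dim(Xp), c(3, 37))
})

test_that("mse_loss matches closed forms and the loop oracle", {
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(mse_loss(X, X), 0)
  expect_equal(mse_loss(matrix(0, 5, 2), matrix(1, 5, 2)), 1)
  Y <- matrix(rnorm(12), 3, 4)
  acc <- 0
  for (i in 1:3) for (j in 1:4) acc <- acc + (X[i, j] - Y[i, j])^2
  expect_equal(mse_loss(X, Y), acc / 12, tolerance = 1e-12)
  expect_equal(mse_loss(X, Y, variant = "l2"), sqrt(acc), tolerance = 1e-12)
  expect_error(mse_loss(X, Y[, 1:2]), "mismatch")
})

test_that("decoder training freezes the encoder and reproduces
           trajectories", {
  model <- alignment_model(tiny_image_config(),
                           tiny_gene_config(n_genes = 20L),
                           align_cfg = align_config(batch_size = 4L),
                           seed = 4L)
  dec <- expression_decoder(tiny_decoder_config(in_dim = 64L,
                                                n_genes_out = 12L),
                            seed = 5L)
  set.seed(82)
  V <- matrix(rnorm(16 * 64), 16, 64)
  X <- matrix(rnorm(16 * 12), 16, 12)
  expect_error(decoder_training_step(list(V = V, X = X), dec, model, 1L),
               "frozen")
  frozen <- freeze_encoder(model)
  hash_before <- digest_params(frozen$theta$img)
  d1 <- train_decoder(dec, frozen, V, X, steps = 10L, batch_size = 8L,
                      seed = 9L)
  expect_identical(digest_params(frozen$theta$img), hash_before)
  d2 <- train_decoder(dec, frozen, V, X, steps = 10L, batch_size = 8L,
                      seed = 9L)
  expect_identical(d1$log, d2$log)
  expect_identical(d1$params, d2$params)
  # overfit sanity: loss falls substantially on a fixed 16-spot batch
  d200 <- train_decoder(dec, frozen, V, X, steps = 200L, batch_size = 16L,
                        lr = 3e-3, seed = 9L)
  expect_lt(mean(d200$log$mse[191:200]), 0.5 * mean(d200$log$mse[1:5]))
})
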