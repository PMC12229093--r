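# Stage-1 machinery: EMA updates, similarity softmax, pseudo-targets,
# contrastive loss, and the training-step contracts.

test_that("ema_update follows the exponential moving average exactly", {
  mk <- function(beta) list(theta = list(w = 0, m = matrix(0, 2, 2)),
                            theta_m = list(w = 1, m = matrix(1, 2, 2)),
                            beta = beta)
  s <- ema_update(mk(1))
  expect_equal(s$theta_m$w, 1)                     # beta = 1: fixed point
  s <- ema_update(mk(0))
  expect_equal(s$theta_m$m, matrix(0, 2, 2))       # beta = 0: copies theta
  s <- mk(0.995)
  for (t in 1:5) s <- ema_update(s)
  expect_equal(s$theta_m$w, 0.995^5)               # geometric decay
  # structural mismatch is reported by parameter name
  bad <- list(theta = list(w = 0), theta_m = list(w2 = 1), beta = 0.5)
  expect_error(ema_update(bad), "w2")
})

test_that("similarity_softmax matches scalar softmax arithmetic", {
  expect_error(similarity_softmax(diag(2), diag(2), 0), "tau")
  # identical keys: every row uniform
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rep(c(1, 0, 0, 0), 3), 3, 4, byrow = TRUE)
  p <- similarity_softmax(Q, K, 0.07)
  expect_equal(p, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # S = 2 with cosines (1, 0) at tau = 0.07
  Q2 <- matrix(c(1, 0), 1, 2)
  K2 <- rbind(c(1, 0), c(0, 1))
  p2 <- similarity_softmax(Q2, K2, 0.07)
  expect_equal(as.numeric(p2),
               exp(c(1, 0) / 0.07) / sum(exp(c(1, 0) / 0.07)),
               tolerance = 1e-9)
  # tau -> infinity limit: uniform
  expect_equal(as.numeric(similarity_softmax(Q2, K2, 1e9)), c(0.5, 0.5),
               tolerance = 1e-6)
})

test_that("pseudo-targets mix the momentum distribution with identity", {
  expect_equal(build_pseudo_targets(rand_stochastic(4), 0), diag(4))
  pm <- rand_stochastic(5)
  expect_equal(build_pseudo_targets(pm, 1), pm)
  y <- build_pseudo_targets(matrix(0.25, 4, 4), 0.4)
  expect_equal(diag(y), rep(0.7, 4))
  expect_equal(y[1, 2], 0.1)
  expect_error(build_pseudo_targets(pm, 1.2), "alpha")
})

test_that("contrastive loss reproduces closed forms", {
  onehot <- diag(4)
  expect_lt(contrastive_loss(onehot, onehot, onehot, onehot), 1e-10)
  unif <- matrix(0.25, 4, 4)
  expect_equal(contrastive_loss(unif, unif, onehot, onehot), log(4))
  # never NaN even with zero probabilities against positive targets
  z <- cbind(c(1, 1, 1, 1), matrix(0, 4, 3))
  expect_true(is.finite(contrastive_loss(z, z, unif, unif)))
})

test_that("lr = 0 leaves primary parameters bitwise unchanged while the
           momentum copy still moves", {
  sl <- tiny_slice(rng_seed = 51L, grid = c(3L, 3L), n_genes = 40L)
  panel <- select_hvg(normalize_expression(sl$counts), sl$gene_names,
                      k = 24L)
  m <- alignment_model(tiny_image_config(),
                       tiny_gene_config(n_genes = 24L),
                       align_cfg = align_config(batch_size = 4L))
  # push theta_m away from theta so the EMA move is observable
  m$theta_m <- histex:::tree_map(function(x) x + 0.1, m$theta_m)
  x <- panel_matrix(normalize_expression(sl$counts), panel)
  patches <- resize_patches(sl$patches[1:4], 32L)
  before <- m$theta
  before_m <- m$theta_m
  out <- alignment_training_step(list(patches = patches, x = x[1:4, ]),
                                 m, rng_seed = 3L, lr = 0)
  expect_identical(out$model$theta, before)
  d_before <- histex:::tree_dist2(before_m, before)
  d_after <- histex:::tree_dist2(out$model$theta_m,
                                 out$model$theta[c("img", "gene")])
  expect_equal(sqrt(d_after / d_before), 0.995, tolerance = 1e-9)
  expect_error(alignment_training_step(
    list(patches = patches[1], x = x[1, , drop = FALSE]), m, 1L),
    ">= 2")
})

test_that("training trajectories are identical under identical seeds and
           the loss falls when overfitting a fixed tiny batch", {
  sl <- tiny_slice(rng_seed = 52L, grid = c(3L, 3L), n_genes = 40L)
  panel <- select_hvg(normalize_expression(sl$counts), sl$gene_names,
                      k = 24L)
  mk <- function() alignment_model(
    tiny_image_config(), tiny_gene_config(n_genes = 24L),
    align_cfg = align_config(batch_size = 8L, lr = 2e-3, steps = 50L,
                             seed = 9L, augment = FALSE))
  m1 <- train_alignment(mk(), sl, panel, spots = 1:8)
  m2 <- train_alignment(mk(), sl, panel, spots = 1:8)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$theta, m2$theta)
  first <- mean(m1$log$total[1:5])
  last <- mean(m1$log$total[46:50])
  expect_lt(last, first)
})
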