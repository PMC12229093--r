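# Fusion (self-attention + cross-attention + FFN) and the image-gene
# matching head.

test_that("self-attention reduces to LayerNorm(input) with zero
           projections", {
  fus <- fusion_module(fusion_config(dim = 8L, heads = 2L), seed = 3L)
  z <- fus
  z$params$blocks[[1]]$self <- histex:::tree_map(
    function(x) x * 0, z$params$blocks[[1]]$self)
  x <- matrix(rnorm(40), 5, 8)
  got <- self_attend(x, z)
  tp <- histex:::tape_new()
  ln <- histex:::ad_layernorm_rows(
    tp, histex:::ad_const(tp, x),
    histex:::ad_const(tp, z$params$blocks[[1]]$ln_self$g),
    histex:::ad_const(tp, z$params$blocks[[1]]$ln_self$b))$v
  expect_equal(got, ln, tolerance = 1e-12)
  expect_equal(dim(self_attend(x, fus)), dim(x))
})

test_that("single-token attention puts weight exactly 1 on itself", {
  p <- histex:::init_mha(6L, 6L, 6L, 2L)
  x <- matrix(rnorm(6), 1, 6)
  tp <- histex:::tape_new()
  pn <- histex:::tree_nodes(tp, p, FALSE)
  out <- histex:::nn_mha(tp, histex:::ad_const(tp, x),
                         histex:::ad_const(tp, x), pn, 2L)$v
  # with one key the softmax weight is 1, so attention = Wo(Wv x)
  lin <- function(x, l) sweep(x %*% l$W, 2L, l$b, "+")
  expect_equal(out, lin(lin(x, p$Wv), p$Wo), tolerance = 1e-12)
})

test_that("cross-attention is convex over identical values and matches the
           naive oracle", {
  set.seed(61)
  # identical key/value rows: the attention output is that value for any Q
  p <- histex:::init_mha(6L, 6L, 6L, 2L)
  kv <- matrix(rep(rnorm(6), each = 4), 4, 6)
  lin <- function(x, l) sweep(x %*% l$W, 2L, l$b, "+")
  for (s in 1:3) {
    xq <- matrix(rnorm(18), 3, 6)
    tp <- histex:::tape_new()
    pn <- histex:::tree_nodes(tp, p, FALSE)
    out <- histex:::nn_mha(tp, histex:::ad_const(tp, xq),
                           histex:::ad_const(tp, kv), pn, 2L)$v
    expected <- lin(matrix(rep(lin(kv, p$Wv)[1, ], each = 3), 3, 6), p$Wo)
    expect_equal(out, expected, tolerance = 1e-10)
  }
  # full cross_fuse block against an independently coded oracle
  fus <- fusion_module(fusion_config(dim = 8L, heads = 2L), seed = 4L)
  blk <- fus$params$blocks[[1]]
  zs <- matrix(rnorm(32), 4, 8)
  vf <- matrix(rnorm(24), 3, 8)
  got <- cross_fuse(zs, vf, fus)
  ln <- function(x, l) {
    mu <- rowMeans(x); xc <- x - mu
    xh <- xc / sqrt(rowMeans(xc^2) + 1e-5)
    sweep(sweep(xh, 2, l$g, "*"), 2, l$b, "+")
  }
  zc <- ln(zs + naive_mha(zs, vf, blk$cross, 2L), blk$ln_cross)
  lin2 <- function(x, l) sweep(x %*% l$W, 2L, l$b, "+")
  ffn <- lin2(pmax(lin2(zc, blk$ffn1), 0), blk$ffn2)
  expect_equal(got, ln(zc + ffn, blk$ln_out), tolerance = 1e-8)
  expect_error(cross_fuse(zs, vf[, 1:4], fus), "dim")
})

test_that("hard-negative mining is a masked argmax with index ties", {
  expect_equal(mine_hard_negatives(diag(2)), c(2L, 1L))
  # diagonal never selected even when it dominates
  m <- diag(3) * 10 + 0.1
  expect_false(any(mine_hard_negatives(m) == 1:3))
  set.seed(62)
  r <- matrix(runif(36), 6, 6)
  oracle <- vapply(1:6, function(i) {
    v <- r[i, ]; v[i] <- -Inf
    which(v == max(v))[1]
  }, integer(1))
  expect_equal(mine_hard_negatives(r), oracle)
  expect_error(mine_hard_negatives(matrix(1, 1, 1)), "at least 2")
})

test_that("igm_loss matches closed forms and a per-element oracle", {
  # p = 0.5 everywhere
  expect_equal(as.numeric(igm_loss(rep(0, 6), rep(c(0, 1), 3))), log(2))
  # confident correct predictions drive the loss to zero
  expect_lt(as.numeric(igm_loss(c(50, -50), c(1, 0))), 1e-10)
  set.seed(63)
  logits <- rnorm(10, sd = 2)
  labels <- rbinom(10, 1, 0.5)
  p <- 1 / (1 + exp(-logits))
  oracle <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  expect_equal(as.numeric(igm_loss(logits, labels)), oracle,
               tolerance = 1e-6)
  expect_equal(attr(igm_loss(logits, labels), "sum"), oracle * 10,
               tolerance = 1e-6)
  # invariant to simultaneous permutation
  perm <- sample(10)
  expect_equal(as.numeric(igm_loss(logits[perm], labels[perm])),
               as.numeric(igm_loss(logits, labels)))
  expect_error(igm_loss(logits, labels + 0.5), "0 or 1")
})

test_that("fused output is finite across random seeds", {
  fus <- fusion_module(fusion_config(dim = 8L, heads = 2L), seed = 5L)
  for (s in 1:20) {
    set.seed(s)
    out <- cross_fuse(matrix(rnorm(24, sd = 3), 3, 8),
                      matrix(rnorm(16, sd = 3), 2, 8), fus)
    expect_true(all(is.finite(out)))
  }
})
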