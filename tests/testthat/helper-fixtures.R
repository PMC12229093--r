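# Shared fixtures. Expensive artifacts (the stage-1 trained model) are
# built once per test run and reused across files.

.hx_cache <- new.env(parent = emptyenv())

tiny_slice <- function(rng_seed = 3L, grid = c(6L, 6L), n_genes = 60L) {
  generate_slice(synthetic_spec(grid_shape = grid, n_genes = n_genes,
                                rng_seed = rng_seed))$slice
}

# study-condition training data: 256 training spots, 64 held-out spots,
# shared planted loading matrix
recovery_data <- function() {
  if (is.null(.hx_cache$recovery)) {
    train <- generate_slice(synthetic_spec(grid_shape = c(16L, 16L),
                                           n_genes = 200L,
                                           rng_seed = 101L))$slice
    heldout <- generate_slice(synthetic_spec(grid_shape = c(8L, 8L),
                                             n_genes = 200L,
                                             rng_seed = 202L))$slice
    panel <- select_hvg(normalize_expression(train$counts),
                        train$gene_names, k = 64L)
    .hx_cache$recovery <- list(train = train, heldout = heldout,
                               panel = panel)
  }
  .hx_cache$recovery
}

# tiny-configuration stage-1 model trained for 300 steps (depth 2,
# width 64), reused by the alignment-recovery and decoder tests
trained_alignment <- function() {
  if (is.null(.hx_cache$aligned)) {
    dat <- recovery_data()
    model <- alignment_model(
      tiny_image_config(), tiny_gene_config(n_genes = 64L),
      align_cfg = align_config(batch_size = 16L, steps = 300L, lr = 3e-3,
                               warmup_steps = 100L, seed = 7L))
    .hx_cache$aligned <- train_alignment(model, dat$train, dat$panel)
  }
  .hx_cache$aligned
}

digest_params <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL), f)
  unname(tools::md5sum(f))
}

rand_stochastic <- function(S) {
  m <- matrix(stats::runif(S * S), S, S)
  m / rowSums(m)
}

# naive three-loop multi-head attention oracle (independent of nn_mha)
naive_mha <- function(xq, xkv, p, heads) {
  lin <- function(x, l) sweep(x %*% l$W, 2L, l$b, "+")
  q <- lin(xq, p$Wq); k <- lin(xkv, p$Wk); v <- lin(xkv, p$Wv)
  d <- ncol(q); dh <- d / heads
  out <- matrix(0, nrow(xq), d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(nrow(xq))) {
      sc <- numeric(nrow(xkv))
      for (j in seq_len(nrow(xkv)))
        sc[j] <- sum(q[i, cols] * k[j, cols]) / sqrt(dh)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      for (j in seq_len(nrow(xkv)))
        out[i, cols] <- out[i, cols] + w[j] * v[j, cols]
    }
  }
  lin(out, p$Wo)
}
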