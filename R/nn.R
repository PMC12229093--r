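# Neural-network building blocks over the autodiff tape: parameter trees,
# initializers, linear / layer-norm / multi-head attention / transformer
# blocks, and a decoupled-weight-decay Adam optimizer.
#
# A "parameter tree" is a nested named list whose leaves are numeric arrays.
# The same nesting is mirrored by node trees on a tape during a forward pass,
# so gradients can be read back leaf-by-leaf.

## ---- parameter tree utilities ----

is_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tree) {
  if (is_leaf(tree)) return(f(tree))
  lapply(tree, tree_map, f = f)
}

tree_map2 <- function(f, a, b) {
  if (is_leaf(a)) return(f(a, b))
  stats::setNames(lapply(seq_along(a), function(i) tree_map2(f, a[[i]], b[[i]])),
                  names(a))
}

tree_flatten <- function(tree, prefix = "") {
  if (is_leaf(tree)) return(stats::setNames(list(tree), prefix))
  out <- list()
  for (nm in names(tree)) {
    sub <- tree_flatten(tree[[nm]],
                        if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
    out <- c(out, sub)
  }
  out
}

# Sum of squared differences between two structurally identical trees
tree_dist2 <- function(a, b) {
  fa <- tree_flatten(a); fb <- tree_flatten(b)
  sum(vapply(seq_along(fa), function(i) sum((fa[[i]] - fb[[i]])^2), numeric(1)))
}

# Wrap every leaf of a parameter tree as a tape node
tree_nodes <- function(tp, tree, trainable = TRUE) {
  tree_map(function(x) if (trainable) ad_leaf(tp, x) else ad_const(tp, x), tree)
}

# Extract accumulated gradients from a node tree (zeros where untouched)
tree_grads <- function(nodes) {
  if (is.environment(nodes)) {
    g <- nodes$g
    if (is.null(g)) g <- array(0, dim = dim_of(nodes$v))
    if (is.null(dim(nodes$v))) g <- as.numeric(g)
    return(g)
  }
  lapply(nodes, tree_grads)
}

## ---- initialization ----

rmat <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)

init_linear <- function(d_in, d_out) {
  list(W = rmat(d_in, d_out, sd = sqrt(2 / (d_in + d_out))),
       b = numeric(d_out))
}

init_ln <- function(d) list(g = rep(1, d), b = numeric(d))

init_mha <- function(d_q, d_kv, d, heads) {
  stopifnot(d %% heads == 0)
  list(Wq = init_linear(d_q, d), Wk = init_linear(d_kv, d),
       Wv = init_linear(d_kv, d), Wo = init_linear(d, d))
}

init_block <- function(d, heads, ffn_hidden) {
  list(attn = init_mha(d, d, d, heads),
       ln1 = init_ln(d),
       ffn1 = init_linear(d, ffn_hidden),
       ffn2 = init_linear(ffn_hidden, d),
       ln2 = init_ln(d))
}

## ---- layers ----

nn_linear <- function(tp, x, p) ad_linear_op(tp, x, p$W, p$b)

nn_layernorm <- function(tp, x, p) ad_layernorm_rows(tp, x, p$g, p$b)

# Multi-head scaled dot-product attention; xq: Tq x d_q, xkv: Tkv x d_kv.
# Self-attention when xkv is xq.
nn_mha <- function(tp, xq, xkv, p, heads) {
  q <- nn_linear(tp, xq, p$Wq)
  k <- nn_linear(tp, xkv, p$Wk)
  v <- nn_linear(tp, xkv, p$Wv)
  d <- ncol(q$v)
  dh <- d %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- ad_cols(tp, q, idx)
    kh <- ad_cols(tp, k, idx)
    vh <- ad_cols(tp, v, idx)
    sc <- ad_scale(tp, ad_matmul(tp, qh, ad_t(tp, kh)), 1 / sqrt(dh))
    a <- ad_softmax_rows(tp, sc)
    outs[[h]] <- ad_matmul(tp, a, vh)
  }
  cat_ <- if (heads == 1L) outs[[1L]] else ad_cbind(tp, outs)
  nn_linear(tp, cat_, p$Wo)
}

nn_ffn <- function(tp, x, p1, p2) {
  nn_linear(tp, ad_relu(tp, nn_linear(tp, x, p1)), p2)
}

# Post-norm transformer encoder block:
#   x1 = LN(x + MHA(x)); x2 = LN(x1 + FFN(x1))
nn_block <- function(tp, x, p, heads) {
  x1 <- nn_layernorm(tp, ad_add(tp, x, nn_mha(tp, x, x, p$attn, heads)), p$ln1)
  nn_layernorm(tp, ad_add(tp, x1, nn_ffn(tp, x1, p$ffn1, p$ffn2)), p$ln2)
}

# Batched variants: x holds S stacked token blocks of length T as rows of a
# single (S*T) x d matrix, so linear/LayerNorm ops run once per layer and
# only the attention softmax is block-diagonal.
nn_mha_batched <- function(tp, xq, xkv, p, heads, S, Tq, Tkv) {
  q <- nn_linear(tp, xq, p$Wq)
  k <- nn_linear(tp, xkv, p$Wk)
  v <- nn_linear(tp, xkv, p$Wv)
  nn_linear(tp, ad_attention_op(tp, q, k, v, S, Tq, Tkv, heads), p$Wo)
}

nn_block_batched <- function(tp, x, p, heads, S, T) {
  x1 <- nn_layernorm(tp, ad_add(tp, x, nn_mha_batched(tp, x, x, p$attn,
                                                      heads, S, T, T)),
                     p$ln1)
  nn_layernorm(tp, ad_add(tp, x1, nn_ffn(tp, x1, p$ffn1, p$ffn2)), p$ln2)
}

# Dropout: keep-mask drawn from the current RNG stream; identity in eval mode.
nn_dropout <- function(tp, x, rate, train) {
  if (!train || rate <= 0) return(x)
  keep <- array(stats::rbinom(length(x$v), 1L, 1 - rate), dim = dim_of(x$v))
  ad_mul_const(tp, x, keep / (1 - rate))
}

## ---- AdamW ----

adamw_new <- function(params, lr = 1e-4, weight_decay = 0.02,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = tree_map(function(x) array(0, dim = dim_of(x)), params),
       v = tree_map(function(x) array(0, dim = dim_of(x)), params),
       t = 0L, lr = lr, wd = weight_decay,
       b1 = beta1, b2 = beta2, eps = eps)
}

adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) opt$b1 * m + (1 - opt$b1) * g, opt$m, grads)
  opt$v <- tree_map2(function(v, g) opt$b2 * v + (1 - opt$b2) * g^2, opt$v, grads)
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + opt$eps),
                   opt$m, opt$v)
  params <- tree_map2(function(p, u) {
    pn <- p - opt$lr * u - opt$lr * opt$wd * p
    if (is.null(dim(p))) pn <- as.numeric(pn)
    pn
  }, params, upd)
  list(opt = opt, params = params)
}

## ---- seeded randomness ----

#' Derive a per-stage integer seed from a global seed and a label
#'
#' A small deterministic hash keeps independently seeded stages reproducible
#' from one pipeline-level seed. Result is always in [1, 2^31 - 2].
#' @param seed integer global seed
#' @param tag character label naming the consumer
#' @return integer seed
#' @export
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
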