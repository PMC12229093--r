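# Multimodal fusion and the image-gene matching (IGM) head. Gene token
# features pass through self-attention, then cross-attention in which the
# histology tokens serve as Key and Value, then a residual feedforward
# block; every residual is followed by LayerNorm. A two-layer MLP on the
# first fused token scores each histology-expression pair as matched or
# not, with the hardest in-batch negatives mined from momentum-encoder
# similarities.

#' Fusion module configuration
#'
#' @param dim channel width; must match both encoders' token width
#' @param heads attention heads
#' @param ffn_hidden feedforward hidden width
#' @param n_blocks number of fusion blocks (the default single block follows
#'   the self-attention / cross-attention / FFN chain once)
#' @param symmetric_negatives mine hardest negatives in both directions
#'   (hardest image per expression profile and hardest profile per image);
#'   the default mines only the hardest image per expression profile
#' @return a `fusion_config`
#' @export
fusion_config <- function(dim = 64L, heads = 2L, ffn_hidden = 2L * dim,
                          n_blocks = 1L, symmetric_negatives = FALSE) {
  stopifnot(dim %% heads == 0, n_blocks >= 1L)
  structure(list(dim = as.integer(dim), heads = as.integer(heads),
                 ffn_hidden = as.integer(ffn_hidden),
                 n_blocks = as.integer(n_blocks),
                 symmetric_negatives = isTRUE(symmetric_negatives)),
            class = "fusion_config")
}

init_fusion <- function(cfg) {
  list(blocks = lapply(seq_len(cfg$n_blocks), function(i) list(
    self = init_mha(cfg$dim, cfg$dim, cfg$dim, cfg$heads),
    ln_self = init_ln(cfg$dim),
    cross = init_mha(cfg$dim, cfg$dim, cfg$dim, cfg$heads),
    ln_cross = init_ln(cfg$dim),
    ffn1 = init_linear(cfg$dim, cfg$ffn_hidden),
    ffn2 = init_linear(cfg$ffn_hidden, cfg$dim),
    ln_out = init_ln(cfg$dim))))
}

init_igm_head <- function(dim) {
  list(fc1 = init_linear(dim, dim), fc2 = init_linear(dim, 1L))
}

# tape-level: Z_self = LayerNorm(x + SelfAttention(x))
fwd_self_attend <- function(tp, blk, x, heads) {
  nn_layernorm(tp, ad_add(tp, x, nn_mha(tp, x, x, blk$self, heads)),
               blk$ln_self)
}

# tape-level: Z_cross = LN(Z_self + CrossAttn(Q = Z_self, K = V = image));
# Z = LN(Z_cross + FFN(Z_cross))
fwd_cross_fuse <- function(tp, blk, z_self, v_feat, heads) {
  zc <- nn_layernorm(tp, ad_add(tp, z_self,
                                nn_mha(tp, z_self, v_feat, blk$cross, heads)),
                     blk$ln_cross)
  nn_layernorm(tp, ad_add(tp, zc, nn_ffn(tp, zc, blk$ffn1, blk$ffn2)),
               blk$ln_out)
}

fwd_igm_logit <- function(tp, pn, pooled) {
  nn_linear(tp, ad_relu(tp, nn_linear(tp, pooled, pn$fc1)), pn$fc2)
}

#' Create a seeded fusion + IGM module
#'
#' @param config a [fusion_config()]
#' @param seed initialization seed
#' @return an `hx_fusion` object
#' @export
fusion_module <- function(config = fusion_config(), seed = 1L) {
  params <- with_seed(seed, c(init_fusion(config),
                              list(igm = init_igm_head(config$dim))))
  structure(list(config = config, params = params), class = "hx_fusion")
}

apply_tokenwise <- function(x, f) {
  if (length(dim(x)) == 3L) {
    out <- array(0, dim(x))
    for (i in seq_len(dim(x)[1])) out[i, , ] <- f(x[i, , ])
    out
  } else f(x)
}

#' Self-attention over gene token features
#'
#' Computes `LayerNorm(x + Attention(x))` with the fusion module's first
#' block. Accepts a single tokens x dim matrix or a batch x tokens x dim
#' array.
#'
#' @param E_feat gene token features
#' @param fusion an `hx_fusion`
#' @return array of the same shape
#' @export
self_attend <- function(E_feat, fusion) {
  cfg <- fusion$config
  blk <- fusion$params$blocks[[1]]
  apply_tokenwise(E_feat, function(m) {
    tp <- tape_new()
    fwd_self_attend(tp, tree_nodes(tp, blk, FALSE), ad_const(tp, m),
                    cfg$heads)$v
  })
}

#' Cross-attention fusion of gene and image features
#'
#' The gene-side `Z_self` supplies the Query; the histology tokens supply
#' Key and Value. A residual feedforward block with LayerNorm follows.
#'
#' @param Z_self gene-side tokens x dim matrix (or batch array)
#' @param V_feat image tokens x dim matrix (or batch array)
#' @param fusion an `hx_fusion`
#' @return fused representation, same shape as `Z_self`
#' @export
cross_fuse <- function(Z_self, V_feat, fusion) {
  cfg <- fusion$config
  blk <- fusion$params$blocks[[1]]
  if (length(dim(Z_self)) == 3L) {
    out <- array(0, dim(Z_self))
    for (i in seq_len(dim(Z_self)[1]))
      out[i, , ] <- cross_fuse(Z_self[i, , ], V_feat[i, , ], fusion)
    return(out)
  }
  if (ncol(Z_self) != cfg$dim || ncol(V_feat) != cfg$dim)
    stop("feature width ", ncol(Z_self), "/", ncol(V_feat),
         " does not match fusion dim ", cfg$dim)
  tp <- tape_new()
  fwd_cross_fuse(tp, tree_nodes(tp, blk, FALSE), ad_const(tp, Z_self),
                 ad_const(tp, V_feat), cfg$heads)$v
}

#' Mine the hardest in-batch negative for each row
#'
#' For each expression profile `i`, returns the index of the most similar
#' non-paired image, `argmax_{j != i} sim[i, j]`, with ties broken by the
#' smallest index.
#'
#' @param sim S x S similarity matrix (rows: expression, cols: images)
#' @param rng_seed unused by the deterministic argmax rule; kept so callers
#'   can pass a seed uniformly across mining strategies
#' @return integer vector of negative indices, one per row
#' @export
mine_hard_negatives <- function(sim, rng_seed = NULL) {
  S <- nrow(sim)
  if (S < 2L) stop("need at least 2 rows to mine negatives")
  vapply(seq_len(S), function(i) {
    r <- sim[i, ]
    r[i] <- -Inf
    which.max(r)
  }, integer(1))
}

#' Binary cross-entropy loss of the IGM head
#'
#' Mean binary cross-entropy of `sigmoid(logits)` against 0/1 labels; the
#' batch-sum variant is attached as attribute `"sum"`.
#'
#' @param logits numeric vector of raw scores
#' @param labels 0/1 vector of the same length
#' @return scalar loss (mean over pairs)
#' @export
igm_loss <- function(logits, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(logits) != length(labels)) stop("logits/labels length mismatch")
  # numerically stable BCE-with-logits
  per <- pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits)))
  out <- mean(per)
  attr(out, "sum") <- sum(per)
  out
}
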