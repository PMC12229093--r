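# The two modality encoders. The image encoder is a ViT: fixed-size patch
# tokens, a learned class token and positional embeddings, transformer
# blocks, and a linear projection of the class token into the shared
# embedding space. The gene encoder follows the scBERT-style chain: each
# gene becomes a token (gene-identity embedding + binned-value embedding),
# a transformer backbone contextualizes the tokens, a 2D convolution with
# kernel (7,5) and padding (0,2) runs over the token x embedding map, global
# average pooling collapses tokens and channels, and a three-layer fully
# connected head with ReLU and dropout emits the embedding.

#' Image (ViT) encoder configuration
#'
#' Defaults correspond to a ViT-B/32-class encoder; the tiny preset used in
#' tests shrinks depth and width so a forward+backward pass runs in well
#' under a second on one CPU.
#'
#' @param input_resolution input side length in pixels
#' @param vit_patch_size ViT token patch size in pixels
#' @param depth number of transformer blocks
#' @param heads attention heads
#' @param width token channel width
#' @param embed_dim shared embedding dimension (default 512)
#' @param ffn_mult feedforward hidden multiple of `width`
#' @return an `image_encoder_config`
#' @export
image_encoder_config <- function(input_resolution = 224L,
                                 vit_patch_size = 32L, depth = 12L,
                                 heads = 12L, width = 768L,
                                 embed_dim = 512L, ffn_mult = 4L) {
  stopifnot(input_resolution %% vit_patch_size == 0, embed_dim > 0,
            width %% heads == 0)
  structure(list(input_resolution = as.integer(input_resolution),
                 vit_patch_size = as.integer(vit_patch_size),
                 depth = as.integer(depth), heads = as.integer(heads),
                 width = as.integer(width), embed_dim = as.integer(embed_dim),
                 ffn_hidden = as.integer(width * ffn_mult)),
            class = "image_encoder_config")
}

#' Gene-expression encoder configuration
#'
#' @param n_genes input panel size (default 2000 highly variable genes)
#' @param backbone_layers transformer backbone depth (default 12)
#' @param backbone_heads attention heads (default 8)
#' @param width token embedding width
#' @param n_bins expression-value bins for the value embedding
#' @param conv_kernel 2D convolution kernel over the token x embedding map
#' @param conv_padding convolution padding (rows, cols)
#' @param conv_channels convolution output channels (default 1)
#' @param dropout dropout rate after the fully connected head (default 0.5)
#' @param embed_dim shared embedding dimension (default 512)
#' @param ffn_mult feedforward hidden multiple of `width`
#' @return a `gene_encoder_config`
#' @export
gene_encoder_config <- function(n_genes = 2000L, backbone_layers = 12L,
                                backbone_heads = 8L, width = 128L,
                                n_bins = 8L, conv_kernel = c(7L, 5L),
                                conv_padding = c(0L, 2L),
                                conv_channels = 1L, dropout = 0.5,
                                embed_dim = 512L, ffn_mult = 2L) {
  stopifnot(dropout >= 0, dropout < 1, all(conv_kernel >= 1),
            all(conv_padding >= 0), width %% backbone_heads == 0,
            n_genes - conv_kernel[1] + 1 + 2 * conv_padding[1] >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 backbone_layers = as.integer(backbone_layers),
                 backbone_heads = as.integer(backbone_heads),
                 width = as.integer(width), n_bins = as.integer(n_bins),
                 conv_kernel = as.integer(conv_kernel),
                 conv_padding = as.integer(conv_padding),
                 conv_channels = as.integer(conv_channels),
                 dropout = dropout, embed_dim = as.integer(embed_dim),
                 ffn_hidden = as.integer(width * ffn_mult)),
            class = "gene_encoder_config")
}

#' Tiny CPU configurations for tests and examples
#'
#' @param n_genes gene panel size for the gene encoder
#' @param embed_dim shared embedding dimension
#' @return a config object
#' @export
tiny_image_config <- function(embed_dim = 64L) {
  image_encoder_config(input_resolution = 32L, vit_patch_size = 16L,
                       depth = 2L, heads = 2L, width = 64L,
                       embed_dim = embed_dim, ffn_mult = 2L)
}

#' @rdname tiny_image_config
#' @export
tiny_gene_config <- function(n_genes = 64L, embed_dim = 64L) {
  # dropout is lowered from the full-scale 0.5: a few-hundred-step
  # desk-scale run is under- rather than over-fit
  gene_encoder_config(n_genes = n_genes, backbone_layers = 2L,
                      backbone_heads = 2L, width = 64L, n_bins = 8L,
                      dropout = 0.1, embed_dim = embed_dim, ffn_mult = 2L)
}

## ---- parameter initialization ----

init_image_encoder <- function(cfg) {
  np <- cfg$input_resolution %/% cfg$vit_patch_size
  t_img <- np * np
  d_in <- 3L * cfg$vit_patch_size^2
  list(patch_embed = init_linear(d_in, cfg$width),
       cls = rmat(1L, cfg$width, 0.02),
       pos = rmat(t_img + 1L, cfg$width, 0.02),
       blocks = lapply(seq_len(cfg$depth), function(i)
         init_block(cfg$width, cfg$heads, cfg$ffn_hidden)),
       ln_f = init_ln(cfg$width),
       proj = init_linear(cfg$width, cfg$embed_dim))
}

init_gene_encoder <- function(cfg) {
  kh <- cfg$conv_kernel[1]; kw <- cfg$conv_kernel[2]
  conv_w <- array(stats::rnorm(kh * kw * cfg$conv_channels,
                               sd = sqrt(2 / (kh * kw))),
                  c(kh, kw, cfg$conv_channels))
  # GAP averages across the embedding/channel axis, leaving one value per
  # post-convolution gene token
  gap_dim <- cfg$n_genes - kh + 1L + 2L * cfg$conv_padding[1]
  list(gene_embed = rmat(cfg$n_genes, cfg$width, 0.02),
       value_embed = rmat(cfg$n_bins + 1L, cfg$width, 0.02),
       blocks = lapply(seq_len(cfg$backbone_layers), function(i)
         init_block(cfg$width, cfg$backbone_heads, cfg$ffn_hidden)),
       conv_w = conv_w, conv_b = numeric(cfg$conv_channels),
       fc1 = init_linear(gap_dim, cfg$width),
       fc2 = init_linear(cfg$width, cfg$width),
       fc3 = init_linear(cfg$width, cfg$embed_dim))
}

## ---- input preparation ----

#' Resize a list of patches to an encoder's input resolution
#'
#' @param patches list of RGB arrays
#' @param resolution target side length
#' @return list of resized arrays
#' @export
resize_patches <- function(patches, resolution) {
  lapply(patches, resize_bilinear, out_h = resolution, out_w = resolution)
}

# Stack ViT tokens for a batch: (S * T) x (3 p^2) matrix, tokens row-major
# within each sample, pixel values standardized to [-1, 1].
prep_image_tokens <- function(patches, cfg) {
  res <- cfg$input_resolution
  p <- cfg$vit_patch_size
  np <- res %/% p
  rows <- lapply(patches, function(img) {
    if (!all(dim(img)[1:2] == res))
      stop("patch is ", dim(img)[1], "x", dim(img)[2],
           " but the encoder expects ", res, "x", res,
           "; resize with resize_patches()")
    x <- img / 127.5 - 1
    tok <- matrix(0, np * np, 3L * p * p)
    k <- 0L
    for (py in seq_len(np)) for (px in seq_len(np)) {
      k <- k + 1L
      tok[k, ] <- as.numeric(x[((py - 1L) * p + 1L):(py * p),
                               ((px - 1L) * p + 1L):(px * p), ])
    }
    tok
  })
  list(tokens = do.call(rbind, rows), S = length(patches), T = np * np)
}

# Discretize normalized expression into value bins; 0 keeps its own bin.
bin_expression <- function(x, n_bins) {
  top <- log1p(1e6)
  b <- pmin(floor(x / (top / n_bins)), n_bins - 1L) + 1L
  b[x <= 0] <- 0L
  b
}

## ---- tape-level forwards ----

# pn: node tree of image-encoder params; batch from prep_image_tokens().
# All samples' token sequences are processed as stacked blocks of one
# (S*(T+1)) x width matrix. Returns list(V = S x embed_dim raw embeddings,
# tokens = the stacked post-block token matrix, T1 = tokens per sample).
fwd_image_encoder <- function(tp, pn, cfg, batch, keep_tokens = FALSE) {
  S <- batch$S; T <- batch$T; T1 <- T + 1L
  emb <- nn_linear(tp, ad_const(tp, batch$tokens), pn$patch_embed)
  # interleave the class token before each sample's T patch tokens
  stacked <- ad_rbind(tp, list(ad_rows(tp, pn$cls, rep(1L, S)), emb))
  perm <- integer(S * T1)
  for (i in seq_len(S)) {
    off <- (i - 1L) * T1
    perm[off + 1L] <- i
    perm[off + 1L + seq_len(T)] <- S + (i - 1L) * T + seq_len(T)
  }
  x <- ad_rows(tp, stacked, perm)
  x <- ad_add(tp, x, ad_rows(tp, pn$pos, rep(seq_len(T1), S)))
  for (blk in pn$blocks) x <- nn_block_batched(tp, x, blk, cfg$heads, S, T1)
  x <- nn_layernorm(tp, x, pn$ln_f)
  cls_out <- ad_rows(tp, x, seq(1L, S * T1, by = T1))
  V <- nn_linear(tp, cls_out, pn$proj)
  list(V = V, tokens = if (keep_tokens) x else NULL, T1 = T1)
}

# pn: node tree of gene-encoder params; x: S x n_genes normalized matrix.
# Token blocks (one token per gene) are stacked into a single matrix; the
# convolution + GAP run per sample on that sample's block.
fwd_gene_encoder <- function(tp, pn, cfg, x, train = FALSE,
                             keep_tokens = FALSE) {
  S <- nrow(x)
  G <- cfg$n_genes
  bins <- bin_expression(x, cfg$n_bins)
  vtok <- ad_rows(tp, pn$value_embed, as.integer(t(bins)) + 1L)
  gtok <- ad_rows(tp, pn$gene_embed, rep(seq_len(G), S))
  tok <- ad_add(tp, gtok, vtok)
  for (blk in pn$blocks)
    tok <- nn_block_batched(tp, tok, blk, cfg$backbone_heads, S, G)
  pooled <- vector("list", S)
  for (i in seq_len(S)) {
    blk_i <- ad_rows(tp, tok, ((i - 1L) * G + 1L):(i * G))
    cv <- ad_conv2d(tp, blk_i, pn$conv_w, pn$conv_b,
                    pad = cfg$conv_padding)
    dcv <- dim(cv$v)
    # mean across embedding channels (and conv output channels): one
    # pooled value per post-convolution gene token
    flat <- ad_reshape(tp, cv, c(dcv[1], dcv[2] * dcv[3]))
    pooled[[i]] <- ad_colmeans(tp, ad_t(tp, flat))
  }
  h <- ad_rbind(tp, pooled)
  h <- ad_relu(tp, nn_linear(tp, h, pn$fc1))
  h <- ad_relu(tp, nn_linear(tp, h, pn$fc2))
  h <- ad_relu(tp, nn_linear(tp, h, pn$fc3))
  E <- nn_dropout(tp, h, cfg$dropout, train)
  list(E = E, tokens = if (keep_tokens) tok else NULL)
}

## ---- value-level encoder objects ----

#' Create a seeded image encoder
#'
#' @param config an [image_encoder_config()]
#' @param seed integer initialization seed
#' @return an `hx_image_encoder` (config + parameter tree)
#' @export
image_encoder <- function(config = image_encoder_config(), seed = 1L) {
  params <- with_seed(seed, init_image_encoder(config))
  structure(list(config = config, params = params),
            class = "hx_image_encoder")
}

#' Create a seeded gene-expression encoder
#'
#' @param config a [gene_encoder_config()]
#' @param seed integer initialization seed
#' @return an `hx_gene_encoder`
#' @export
gene_encoder <- function(config = gene_encoder_config(), seed = 1L) {
  params <- with_seed(seed, init_gene_encoder(config))
  structure(list(config = config, params = params),
            class = "hx_gene_encoder")
}

#' Encode image patches into the shared embedding space
#'
#' Patches must already be at the encoder's input resolution (see
#' [resize_patches()]). Evaluation mode is deterministic.
#'
#' @param encoder an `hx_image_encoder`, or any object with `$config` and
#'   `$params` for the image branch
#' @param patches list of RGB arrays at the encoder resolution
#' @param mode `"eval"` or `"train"`
#' @return batch x embed_dim matrix of raw (unnormalized) embeddings
#' @export
encode_image <- function(encoder, patches, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  cfg <- encoder$config
  batch <- prep_image_tokens(patches, cfg)
  tp <- tape_new()
  pn <- tree_nodes(tp, encoder$params, trainable = FALSE)
  fwd_image_encoder(tp, pn, cfg, batch)$V$v
}

#' Encode normalized expression vectors into the shared embedding space
#'
#' @param encoder an `hx_gene_encoder`
#' @param x batch x n_genes matrix of log-normalized expression
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active, drawn
#'   from the current RNG stream)
#' @return batch x embed_dim matrix of raw embeddings
#' @export
encode_expression <- function(encoder, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  cfg <- encoder$config
  x <- as.matrix(x)
  if (ncol(x) != cfg$n_genes)
    stop("expression has ", ncol(x), " genes but the encoder panel has ",
         cfg$n_genes)
  tp <- tape_new()
  pn <- tree_nodes(tp, encoder$params, trainable = FALSE)
  fwd_gene_encoder(tp, pn, cfg, x, train = (mode == "train"))$E$v
}

#' L2-normalize matrix rows
#'
#' @param m numeric matrix
#' @return matrix with unit-norm rows
#' @export
l2_normalize <- function(m) {
  m / sqrt(rowSums(m^2) + 1e-12)
}
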