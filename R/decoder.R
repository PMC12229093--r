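# Stage-2 generative model: the frozen image encoder's embeddings are
# projected to a wider feature, reshaped into a short token sequence, run
# through transformer blocks (multi-head self-attention, add & norm, FFN,
# add & norm), and mapped linearly to the target gene panel. Training
# minimizes mean squared error against log-normalized expression.

#' Decoder configuration
#'
#' @param in_dim frozen-encoder embedding dimension (default 512)
#' @param hidden_dim projection width; must be divisible by `tokens`, and
#'   `hidden_dim / tokens` by `heads`
#' @param n_layers transformer blocks (default 4)
#' @param heads attention heads per block (default 8)
#' @param tokens length of the token sequence the projected feature is
#'   reshaped into (default 8)
#' @param n_genes_out size of the target gene panel (default 300)
#' @param proj_nonlinear apply ReLU between the two projection layers
#' @param ffn_mult feedforward hidden multiple of the token width
#' @return a `decoder_config`
#' @export
decoder_config <- function(in_dim = 512L, hidden_dim = 512L, n_layers = 4L,
                           heads = 8L, tokens = 8L, n_genes_out = 300L,
                           proj_nonlinear = TRUE, ffn_mult = 2L) {
  stopifnot(hidden_dim %% tokens == 0,
            (hidden_dim %/% tokens) %% heads == 0, n_genes_out >= 1L)
  structure(list(in_dim = as.integer(in_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers), heads = as.integer(heads),
                 tokens = as.integer(tokens),
                 token_dim = as.integer(hidden_dim %/% tokens),
                 n_genes_out = as.integer(n_genes_out),
                 proj_nonlinear = isTRUE(proj_nonlinear),
                 ffn_mult = as.integer(ffn_mult)),
            class = "decoder_config")
}

#' @rdname decoder_config
#' @export
tiny_decoder_config <- function(in_dim = 64L, n_genes_out = 50L) {
  decoder_config(in_dim = in_dim, hidden_dim = 64L, n_layers = 2L,
                 heads = 2L, tokens = 4L, n_genes_out = n_genes_out)
}

init_decoder <- function(cfg) {
  half <- max(1L, cfg$hidden_dim %/% 2L)
  list(proj1 = init_linear(cfg$in_dim, half),
       proj2 = init_linear(half, cfg$hidden_dim),
       blocks = lapply(seq_len(cfg$n_layers), function(i)
         init_block(cfg$token_dim, cfg$heads,
                    cfg$ffn_mult * cfg$token_dim)),
       out = init_linear(cfg$hidden_dim, cfg$n_genes_out))
}

#' Create a seeded expression decoder
#'
#' @param config a [decoder_config()]
#' @param panel optional target `gene_panel`; when given, its size must
#'   equal `n_genes_out` and prediction columns are named by it
#' @param seed initialization seed
#' @return an `hx_decoder`
#' @export
expression_decoder <- function(config = decoder_config(), panel = NULL,
                               seed = 1L) {
  if (!is.null(panel) && panel$size != config$n_genes_out)
    stop("panel size (", panel$size, ") must equal n_genes_out (",
         config$n_genes_out, ")")
  params <- with_seed(seed, init_decoder(config))
  structure(list(config = config, params = params, panel = panel,
                 opt = NULL, step = 0L, log = NULL),
            class = "hx_decoder")
}

#' @export
print.hx_decoder <- function(x, ...) {
  cat("<hx_decoder> ", x$config$in_dim, " -> ", x$config$hidden_dim,
      " (", x$config$tokens, " tokens x ", x$config$n_layers,
      " blocks) -> ", x$config$n_genes_out, " genes\n", sep = "")
  invisible(x)
}

## ---- tape-level forward ----

fwd_project <- function(tp, pn, cfg, V) {
  h <- nn_linear(tp, V, pn$proj1)
  if (cfg$proj_nonlinear) h <- ad_relu(tp, h)
  nn_linear(tp, h, pn$proj2)
}

fwd_decode <- function(tp, pn, cfg, Ep) {
  S <- nrow(Ep$v)
  # reshape each sample's hidden vector into a block of `tokens` rows
  x <- ad_t(tp, ad_reshape(tp, ad_t(tp, Ep),
                           c(cfg$token_dim, cfg$tokens * S)))
  for (blk in pn$blocks)
    x <- nn_block_batched(tp, x, blk, cfg$heads, S, cfg$tokens)
  flat <- ad_t(tp, ad_reshape(tp, ad_t(tp, x), c(cfg$hidden_dim, S)))
  nn_linear(tp, flat, pn$out)
}

## ---- value-level operations ----

#' Project frozen-encoder embeddings to the decoder width
#'
#' Two linear layers with an optional ReLU between them.
#'
#' @param decoder an `hx_decoder`
#' @param V batch x in_dim embedding matrix
#' @return batch x hidden_dim matrix `E'`
#' @export
project_features <- function(decoder, V) {
  tp <- tape_new()
  fwd_project(tp, tree_nodes(tp, decoder$params, FALSE), decoder$config,
              ad_const(tp, as.matrix(V)))$v
}

#' Decode projected features into gene expression
#'
#' @param decoder an `hx_decoder`
#' @param E_prime batch x hidden_dim matrix from [project_features()]
#' @return batch x n_genes_out prediction matrix
#' @export
decode_expression <- function(decoder, E_prime) {
  tp <- tape_new()
  out <- fwd_decode(tp, tree_nodes(tp, decoder$params, FALSE),
                    decoder$config, ad_const(tp, as.matrix(E_prime)))$v
  if (!is.null(decoder$panel)) colnames(out) <- decoder$panel$names
  out
}

#' Predict expression from frozen-encoder embeddings
#'
#' @param decoder an `hx_decoder`
#' @param V batch x in_dim embeddings from the frozen image encoder
#' @return batch x n_genes_out predicted log-normalized expression
#' @export
predict_expression <- function(decoder, V) {
  decode_expression(decoder, project_features(decoder, V))
}

#' Mean squared error between expression matrices
#'
#' The mean over all entries of the squared difference; the raw L2-norm
#' reading of the objective is available as `variant = "l2"`.
#'
#' @param X,X_p matrices of identical shape
#' @param variant `"mean"` (default) or `"l2"` (Frobenius norm)
#' @return scalar
#' @export
mse_loss <- function(X, X_p, variant = c("mean", "l2")) {
  variant <- match.arg(variant)
  if (!identical(dim_of(X), dim_of(X_p)))
    stop("shape mismatch: ", paste(dim_of(X), collapse = "x"), " vs ",
         paste(dim_of(X_p), collapse = "x"))
  d <- X - X_p
  if (variant == "mean") mean(d^2) else sqrt(sum(d^2))
}

## ---- training ----

#' One stage-2 training step
#'
#' Updates projection and decoder parameters only; errors unless the
#' encoder that produced the embeddings is flagged frozen (see
#' [freeze_encoder()]).
#'
#' @param batch list with `V` (batch x in_dim embeddings) and `X`
#'   (batch x n_genes_out targets)
#' @param decoder an `hx_decoder`
#' @param frozen_encoder the `hx_alignment` model whose image branch
#'   produced `V`
#' @param rng_seed integer seed for the step
#' @param lr optional learning-rate override
#' @return list with updated `decoder` and the step `loss`
#' @export
decoder_training_step <- function(batch, decoder, frozen_encoder, rng_seed,
                                  lr = 1e-3) {
  if (!isTRUE(frozen_encoder$frozen))
    stop("the image encoder must be frozen before decoder training; ",
         "call freeze_encoder()")
  set.seed(rng_seed)
  cfg <- decoder$config
  tp <- tape_new()
  pn <- tree_nodes(tp, decoder$params, trainable = TRUE)
  Xp <- fwd_decode(tp, pn, cfg,
                   fwd_project(tp, pn, cfg, ad_const(tp, batch$V)))
  L <- ad_mean_all(tp, ad_square(tp, ad_sub(tp, Xp, ad_const(tp, batch$X))))
  ad_backward(tp, L)
  grads <- tree_grads(pn)
  if (is.null(decoder$opt))
    decoder$opt <- adamw_new(decoder$params, lr = lr, weight_decay = 0.02)
  decoder$opt$lr <- lr
  res <- adamw_step(decoder$opt, decoder$params, grads)
  decoder$opt <- res$opt
  decoder$params <- res$params
  decoder$step <- decoder$step + 1L
  list(decoder = decoder, loss = as.numeric(L$v))
}

#' Train the expression decoder on frozen-encoder embeddings
#'
#' @param decoder an `hx_decoder`
#' @param frozen_encoder the frozen `hx_alignment` model (see
#'   [freeze_encoder()])
#' @param V spots x in_dim embeddings of the training spots
#' @param X spots x n_genes_out target log-normalized expression
#' @param steps optimizer steps (default 200)
#' @param batch_size spots per step (default 16)
#' @param lr AdamW learning rate
#' @param seed training seed
#' @return the trained decoder with a per-step `log`
#' @export
train_decoder <- function(decoder, frozen_encoder, V, X, steps = 200L,
                          batch_size = 16L, lr = 1e-3, seed = 1L) {
  stopifnot(nrow(V) == nrow(X), ncol(X) == decoder$config$n_genes_out)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    sseed <- derive_seed(seed, paste0("decode-step-", s))
    set.seed(sseed)
    idx <- sample(nrow(V), min(batch_size, nrow(V)))
    out <- decoder_training_step(
      list(V = V[idx, , drop = FALSE], X = X[idx, , drop = FALSE]),
      decoder, frozen_encoder, rng_seed = derive_seed(sseed, "fwd"),
      lr = lr)
    decoder <- out$decoder
    losses[s] <- out$loss
  }
  decoder$log <- data.frame(step = seq_len(steps), mse = losses)
  decoder
}
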