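# Stage-1 training: momentum-distilled contrastive alignment of histology
# and gene-expression embeddings, plus the image-gene matching objective.
#
# A momentum ("teacher") copy of both encoders is advanced by an
# exponential moving average of the primary parameters. Its softmax
# similarity distributions are mixed with the one-hot pairing matrix to
# form pseudo-targets for a bidirectional cross-entropy contrastive loss.
# The IGM head is trained on true pairs against hardest in-batch negatives
# mined from the momentum similarities.

#' Stage-1 training configuration
#'
#' Defaults follow the method's stated values: momentum coefficient
#' `beta = 0.995`, pseudo-target mixing weight `alpha = 0.4`, softmax
#' temperature `tau = 0.07`.
#'
#' @param beta EMA momentum coefficient in `[0, 1]`
#' @param alpha pseudo-target mixing weight in `[0, 1]`
#' @param tau softmax temperature (> 0)
#' @param lambda_igm weight of the IGM loss relative to the contrastive
#'   loss (default 1)
#' @param batch_size spots per step (>= 2, so in-batch negatives exist)
#' @param lr AdamW learning rate
#' @param weight_decay AdamW decoupled weight decay
#' @param steps optimizer steps
#' @param warmup_steps linear learning-rate warmup length; from-scratch
#'   contrastive training at a sharp temperature collapses to the uniform
#'   saddle without it
#' @param seed training seed; every step's randomness is derived from it
#' @param augment apply seeded patch augmentation during training
#' @return an `align_config`
#' @export
align_config <- function(beta = 0.995, alpha = 0.4, tau = 0.07,
                         lambda_igm = 1, batch_size = 32L, lr = 1e-4,
                         weight_decay = 0.02, steps = 300L,
                         warmup_steps = 50L, seed = 1L,
                         augment = TRUE) {
  stopifnot(beta >= 0, beta <= 1, alpha >= 0, alpha <= 1, tau > 0,
            batch_size >= 2L, steps >= 1L)
  structure(list(beta = beta, alpha = alpha, tau = tau,
                 lambda_igm = lambda_igm,
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, steps = as.integer(steps),
                 warmup_steps = as.integer(warmup_steps),
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "align_config")
}

#' Row-wise softmax over cosine similarities
#'
#' Entry `(i, k)` is `softmax_k(cos(Q_i, K_k) / tau)`; rows sum to one.
#' Rows are L2-normalized internally, so passing unnormalized embeddings is
#' safe.
#'
#' @param Q,K matrices with matching column dimension
#' @param tau temperature, > 0
#' @return row-stochastic matrix of dimension `nrow(Q)` x `nrow(K)`
#' @export
similarity_softmax <- function(Q, K, tau) {
  if (tau <= 0) stop("tau must be > 0")
  s <- l2_normalize(Q) %*% t(l2_normalize(K)) / tau
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

#' Mix momentum similarities with the one-hot pairing matrix
#'
#' Returns `alpha * p_m + (1 - alpha) * I`; since both terms are
#' row-stochastic, so is the mixture.
#'
#' @param p_m S x S row-stochastic momentum similarity matrix
#' @param alpha mixing weight in `[0, 1]`
#' @return S x S row-stochastic pseudo-target matrix
#' @export
build_pseudo_targets <- function(p_m, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (nrow(p_m) != ncol(p_m)) stop("p_m must be square")
  if (max(abs(rowSums(p_m) - 1)) > 1e-6)
    stop("p_m rows must sum to 1")
  alpha * p_m + (1 - alpha) * diag(nrow(p_m))
}

#' Bidirectional contrastive cross-entropy loss
#'
#' `L = 1/2 * mean_i [ CE(y_h2g_i, p_h2g_i) + CE(y_g2h_i, p_g2h_i) ]` with
#' `CE(y, p) = -sum_k y_k log p_k`; probabilities are floored at 1e-12 so
#' zero entries never produce NaN.
#'
#' @param p_h2g,p_g2h predicted row-stochastic similarity matrices
#' @param y_h2g,y_g2h pseudo-target row-stochastic matrices
#' @return scalar loss
#' @export
contrastive_loss <- function(p_h2g, p_g2h, y_h2g, y_g2h) {
  ce <- function(y, p) -rowSums(y * log(pmax(p, 1e-12)))
  0.5 * mean(ce(y_h2g, p_h2g) + ce(y_g2h, p_g2h))
}

## ---- momentum state ----

check_tree_match <- function(a, b) {
  fa <- tree_flatten(a); fb <- tree_flatten(b)
  if (!identical(names(fa), names(fb))) {
    bad <- c(setdiff(names(fa), names(fb)), setdiff(names(fb), names(fa)))
    stop("parameter structure mismatch at: ", paste(bad, collapse = ", "))
  }
  for (nm in names(fa)) {
    if (!identical(dim_of(fa[[nm]]), dim_of(fb[[nm]])))
      stop("parameter shape mismatch at: ", nm)
  }
  invisible(TRUE)
}

#' Exponential moving average update of a momentum parameter copy
#'
#' Replaces every momentum parameter by `beta * old + (1 - beta) * primary`
#' and leaves the primary parameters untouched. Works on any object with
#' fields `theta`, `theta_m`, `beta` (both parameter trees structurally
#' identical) and on fitted alignment models, whose momentum copy covers
#' both encoders including their projection heads.
#'
#' @param state a momentum state or `hx_alignment` model
#' @return the state with `theta_m` updated
#' @export
ema_update <- function(state) UseMethod("ema_update")

#' @export
ema_update.default <- function(state) {
  stopifnot(!is.null(state$theta), !is.null(state$theta_m),
            state$beta >= 0, state$beta <= 1)
  check_tree_match(state$theta, state$theta_m)
  state$theta_m <- tree_map2(function(m, p) state$beta * m +
                               (1 - state$beta) * p,
                             state$theta_m, state$theta)
  state
}

#' @export
ema_update.hx_alignment <- function(state) {
  primary <- state$theta[c("img", "gene")]
  check_tree_match(primary, state$theta_m)
  state$theta_m <- tree_map2(function(m, p) state$beta * m +
                               (1 - state$beta) * p,
                             state$theta_m, primary)
  state
}

## ---- the alignment model ----

#' Create a stage-1 alignment model
#'
#' Bundles the two encoders, the fusion + IGM head, and a momentum copy of
#' both encoders (projection heads included, so momentum similarities live
#' in the same embedding space).
#'
#' @param image_config an [image_encoder_config()]
#' @param gene_config a [gene_encoder_config()]
#' @param fusion_cfg a [fusion_config()]; its `dim` must equal both
#'   encoders' token width
#' @param align_cfg an [align_config()]
#' @param seed initialization seed
#' @return an `hx_alignment` model
#' @export
alignment_model <- function(image_config = tiny_image_config(),
                            gene_config = tiny_gene_config(),
                            fusion_cfg = NULL,
                            align_cfg = align_config(),
                            seed = 1L) {
  if (image_config$width != gene_config$width)
    stop("encoder token widths must match for fusion (",
         image_config$width, " vs ", gene_config$width, ")")
  if (image_config$embed_dim != gene_config$embed_dim)
    stop("encoder embedding dimensions must match")
  if (is.null(fusion_cfg))
    fusion_cfg <- fusion_config(dim = image_config$width,
                                heads = min(2L, image_config$heads))
  if (fusion_cfg$dim != image_config$width)
    stop("fusion dim must equal the encoder token width")
  theta <- with_seed(seed, list(
    img = init_image_encoder(image_config),
    gene = init_gene_encoder(gene_config),
    fusion = init_fusion(fusion_cfg),
    igm = init_igm_head(fusion_cfg$dim)))
  structure(list(config = list(image = image_config, gene = gene_config,
                               fusion = fusion_cfg, align = align_cfg),
                 theta = theta,
                 theta_m = theta[c("img", "gene")],
                 beta = align_cfg$beta,
                 opt = NULL, step = 0L, frozen = FALSE,
                 log = NULL),
            class = "hx_alignment")
}

#' @export
print.hx_alignment <- function(x, ...) {
  cat("<hx_alignment> step ", x$step,
      ", image ", x$config$image$depth, "x", x$config$image$width,
      ", gene ", x$config$gene$backbone_layers, "x", x$config$gene$width,
      " (", x$config$gene$n_genes, " genes), embed ",
      x$config$image$embed_dim, if (x$frozen) ", frozen" else "",
      "\n", sep = "")
  invisible(x)
}

# view a model's branches as standalone encoders
image_branch <- function(model, momentum = FALSE) {
  structure(list(config = model$config$image,
                 params = if (momentum) model$theta_m$img
                          else model$theta$img),
            class = "hx_image_encoder")
}

gene_branch <- function(model, momentum = FALSE) {
  structure(list(config = model$config$gene,
                 params = if (momentum) model$theta_m$gene
                          else model$theta$gene),
            class = "hx_gene_encoder")
}

#' Freeze the encoder parameters of an alignment model
#'
#' Stage-2 decoder training requires a frozen image encoder; this flags the
#' model so downstream training steps can enforce the contract.
#'
#' @param model an `hx_alignment`
#' @return the model, flagged frozen
#' @export
freeze_encoder <- function(model) {
  model$frozen <- TRUE
  model
}

## ---- one optimizer step ----

#' One stage-1 training step
#'
#' Runs primary and momentum forwards on a minibatch, forms pseudo-targets,
#' mines hardest negatives from the momentum similarities, takes one AdamW
#' step on `L_con + lambda * L_IGM`, then EMA-updates the momentum copy.
#' Fully determined by `rng_seed`.
#'
#' @param batch list with `patches` (list of rasters at the encoder
#'   resolution) and `x` (S x n_genes normalized expression)
#' @param model an `hx_alignment`
#' @param rng_seed integer seed for this step's dropout and mining
#' @param lr optional learning-rate override (e.g. 0 to probe the EMA path)
#' @return list with the updated `model` and a `losses` record
#' @export
alignment_training_step <- function(batch, model, rng_seed, lr = NULL) {
  cfg <- model$config
  acfg <- cfg$align
  S <- length(batch$patches)
  if (S < 2L) stop("batch size must be >= 2: no in-batch negatives exist")
  stopifnot(nrow(batch$x) == S)
  set.seed(rng_seed)

  img_batch <- prep_image_tokens(batch$patches, cfg$image)

  # momentum ("teacher") forward, evaluation mode, no gradients
  tpm <- tape_new()
  Vm <- fwd_image_encoder(tpm, tree_nodes(tpm, model$theta_m$img, FALSE),
                          cfg$image, img_batch)$V$v
  Em <- fwd_gene_encoder(tpm, tree_nodes(tpm, model$theta_m$gene, FALSE),
                         cfg$gene, batch$x, train = FALSE)$E$v
  p_m_h2g <- similarity_softmax(Vm, Em, acfg$tau)
  p_m_g2h <- similarity_softmax(Em, Vm, acfg$tau)
  y_h2g <- build_pseudo_targets(p_m_h2g, acfg$alpha)
  y_g2h <- build_pseudo_targets(p_m_g2h, acfg$alpha)

  # hardest negative image for each expression profile, from the momentum
  # similarities of the previous round
  sim_g2i <- l2_normalize(Em) %*% t(l2_normalize(Vm))
  neg_img <- mine_hard_negatives(sim_g2i)

  # primary forward with gradients
  tp <- tape_new()
  pn <- tree_nodes(tp, model$theta, trainable = TRUE)
  fi <- fwd_image_encoder(tp, pn$img, cfg$image, img_batch,
                          keep_tokens = TRUE)
  fg <- fwd_gene_encoder(tp, pn$gene, cfg$gene, batch$x, train = TRUE,
                         keep_tokens = TRUE)
  Vn <- ad_l2norm_rows(tp, fi$V)
  En <- ad_l2norm_rows(tp, fg$E)
  p_h2g <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul(tp, Vn, ad_t(tp, En)),
                                        1 / acfg$tau))
  p_g2h <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul(tp, En, ad_t(tp, Vn)),
                                        1 / acfg$tau))
  ce1 <- ad_scale(tp, ad_sum_all(tp, ad_mul_const(tp, ad_log(tp, p_h2g),
                                                  y_h2g)), -1 / S)
  ce2 <- ad_scale(tp, ad_sum_all(tp, ad_mul_const(tp, ad_log(tp, p_g2h),
                                                  y_g2h)), -1 / S)
  L_con <- ad_scale(tp, ad_add(tp, ce1, ce2), 0.5)

  # IGM: fuse each expression profile's tokens with its paired image and
  # with its hardest-negative image; Z_self is shared between the two.
  # Pairs are processed as stacked token blocks.
  blk <- pn$fusion$blocks[[1]]
  heads <- cfg$fusion$heads
  G <- cfg$gene$n_genes
  T1 <- fi$T1
  z_self <- nn_layernorm(tp, ad_add(tp, fg$tokens,
                                    nn_mha_batched(tp, fg$tokens, fg$tokens,
                                                   blk$self, heads, S, G, G)),
                         blk$ln_self)
  pair_gene <- c(seq_len(S), seq_len(S))
  pair_img <- c(seq_len(S), neg_img)
  labels <- c(rep(1, S), rep(0, S))
  if (cfg$fusion$symmetric_negatives) {
    neg_gene <- mine_hard_negatives(t(sim_g2i))
    pair_gene <- c(pair_gene, neg_gene)
    pair_img <- c(pair_img, seq_len(S))
    labels <- c(labels, rep(0, S))
  }
  P <- length(pair_gene)
  idx_q <- as.integer(outer(seq_len(G), (pair_gene - 1L) * G, "+"))
  idx_kv <- as.integer(outer(seq_len(T1), (pair_img - 1L) * T1, "+"))
  q_all <- ad_rows(tp, z_self, idx_q)
  kv_all <- ad_rows(tp, fi$tokens, idx_kv)
  zc <- nn_layernorm(tp, ad_add(tp, q_all,
                                nn_mha_batched(tp, q_all, kv_all, blk$cross,
                                               heads, P, G, T1)),
                     blk$ln_cross)
  zf <- nn_layernorm(tp, ad_add(tp, zc, nn_ffn(tp, zc, blk$ffn1, blk$ffn2)),
                     blk$ln_out)
  pooled <- ad_rows(tp, zf, seq(1L, P * G, by = G))
  logits <- fwd_igm_logit(tp, pn$igm, pooled)
  p_match <- ad_sigmoid(tp, logits)
  bce <- ad_add(tp,
                ad_mul_const(tp, ad_log(tp, p_match),
                             -matrix(labels)),
                ad_mul_const(tp, ad_log(tp, ad_add_const(
                  tp, ad_mul_const(tp, p_match, -1), 1)),
                  -matrix(1 - labels)))
  L_igm <- ad_mean_all(tp, bce)

  L <- ad_add(tp, L_con, ad_scale(tp, L_igm, acfg$lambda_igm))
  ad_backward(tp, L)
  grads <- tree_grads(pn)

  if (is.null(model$opt))
    model$opt <- adamw_new(model$theta, lr = acfg$lr,
                           weight_decay = acfg$weight_decay)
  step_lr <- lr %||% acfg$lr
  if (step_lr > 0) {
    model$opt$lr <- step_lr
    res <- adamw_step(model$opt, model$theta, grads)
    model$opt <- res$opt
    model$theta <- res$params
  }
  model <- ema_update(model)
  model$step <- model$step + 1L
  list(model = model,
       losses = c(step = model$step, L_con = L_con$v, L_IGM = L_igm_val(L_igm),
                  total = L$v))
}

L_igm_val <- function(node) as.numeric(node$v)

#' Train the stage-1 alignment model on a slice
#'
#' @param model an `hx_alignment`
#' @param slice a `spot_slice` providing patches and counts
#' @param panel the highly-variable `gene_panel` used as encoder input
#' @param steps,batch_size override the model's align config
#' @param seed training seed (default from the align config); per-step
#'   seeds are derived deterministically
#' @param spots optional integer subset of spots to train on
#' @param verbose print a progress line every 50 steps
#' @return the trained model, with a `log` data frame of per-step losses
#' @export
train_alignment <- function(model, slice, panel, steps = NULL,
                            batch_size = NULL, seed = NULL, spots = NULL,
                            verbose = FALSE) {
  acfg <- model$config$align
  steps <- steps %||% acfg$steps
  batch_size <- batch_size %||% acfg$batch_size
  seed <- seed %||% acfg$seed
  res <- model$config$image$input_resolution
  x_all <- panel_matrix(normalize_expression(slice$counts), panel)
  spots <- spots %||% seq_len(slice$n)
  logs <- matrix(0, steps, 4L,
                 dimnames = list(NULL, c("step", "L_con", "L_IGM", "total")))
  for (s in seq_len(steps)) {
    sseed <- derive_seed(seed, paste0("align-step-", s))
    set.seed(sseed)
    idx <- sample(spots, min(batch_size, length(spots)))
    patches <- lapply(seq_along(idx), function(j) {
      p <- slice$patches[[idx[j]]]
      if (acfg$augment)
        p <- augment_patch(p, derive_seed(sseed, paste0("aug", j)))
      resize_bilinear(p, res, res)
    })
    wu <- max(1L, acfg$warmup_steps)
    out <- alignment_training_step(
      list(patches = patches, x = x_all[idx, , drop = FALSE]),
      model, rng_seed = derive_seed(sseed, "fwd"),
      lr = acfg$lr * min(1, s / wu))
    model <- out$model
    logs[s, ] <- out$losses
    if (verbose && s %% 50L == 0L)
      message(sprintf("step %d  L_con %.4f  L_IGM %.4f", s,
                      out$losses["L_con"], out$losses["L_IGM"]))
  }
  model$log <- as.data.frame(logs)
  model
}

#' Embed a slice's patches and expression with a trained model
#'
#' Evaluation-mode (deterministic) embeddings from the primary encoders.
#'
#' @param model an `hx_alignment`
#' @param slice a `spot_slice`
#' @param panel the encoder input `gene_panel`
#' @param spots optional subset of spot indices
#' @return list with raw embedding matrices `V` and `E`
#' @export
embed_slice <- function(model, slice, panel, spots = NULL) {
  spots <- spots %||% seq_len(slice$n)
  res <- model$config$image$input_resolution
  patches <- resize_patches(slice$patches[spots], res)
  x <- panel_matrix(normalize_expression(slice$counts), panel)
  V <- encode_image(image_branch(model), patches)
  E <- encode_expression(gene_branch(model), x[spots, , drop = FALSE])
  list(V = V, E = E)
}
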