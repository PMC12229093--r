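# End-to-end orchestration of the two-stage workflow on synthetic data:
# simulate -> preprocess -> train-align -> train-decode -> predict ->
# evaluate -> wsi. Every stage writes a manifest (inputs, config hash,
# seed, outputs) so each reported number traces to a config and seed, and
# reruns with identical config and inputs are idempotent.

#' Default pipeline configuration
#'
#' The `tiny` preset (the default) sizes every component so the full
#' pipeline runs in minutes on one CPU: 256 training and 64 validation
#' spots, 64-gene encoder panel, 50-gene target panel, depth-2 width-64
#' encoders. `tiny = FALSE` restores the full-scale defaults (2000-gene
#' panel, 300 target genes, ViT-B/32-class encoder sizes).
#'
#' @param seed global seed; every stage derives its own seed from it
#' @param tiny use the desk-scale configuration
#' @return nested configuration list of class `run_config`
#' @export
default_run_config <- function(seed = 1L, tiny = TRUE) {
  cfg <- if (tiny) {
    list(seed = as.integer(seed),
         data = list(train_grid = c(16L, 16L), val_grid = c(8L, 8L),
                     n_genes = 200L, latent_dim = 4L, image_size = 40L,
                     noise_sd = 8, count_depth = 10000,
                     loading_seed = 42L),
         panel = list(hvg = 64L, target = 50L),
         encoders = list(tiny = TRUE),
         align = list(beta = 0.995, alpha = 0.4, tau = 0.07,
                      lambda_igm = 1, batch_size = 16L, lr = 3e-3,
                      weight_decay = 0.02, steps = 300L,
                      warmup_steps = 100L, augment = TRUE),
         decode = list(steps = 200L, batch_size = 64L, lr = 3e-3),
         eval = list(adjacent = c(5L, 10L), random_k = 14L),
         wsi = list(width = 1024L, height = 1024L, tile_size = 256L,
                    n_tiles = 20L, n_tissue_regions = 4L))
  } else {
    list(seed = as.integer(seed),
         data = list(train_grid = c(50L, 50L), val_grid = c(20L, 20L),
                     n_genes = 5000L, latent_dim = 8L, image_size = 40L,
                     noise_sd = 8, count_depth = 10000,
                     loading_seed = 42L),
         panel = list(hvg = 2000L, target = 300L),
         encoders = list(tiny = FALSE),
         align = list(beta = 0.995, alpha = 0.4, tau = 0.07,
                      lambda_igm = 1, batch_size = 32L, lr = 1e-4,
                      weight_decay = 0.02, steps = 5000L,
                      warmup_steps = 500L, augment = TRUE),
         decode = list(steps = 2000L, batch_size = 32L, lr = 1e-4),
         eval = list(adjacent = c(5L, 10L), random_k = 14L),
         wsi = list(width = 4096L, height = 4096L, tile_size = 512L,
                    n_tiles = 20L, n_tissue_regions = 6L))
  }
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed), "seed must be numeric")
  chk(cfg$align$beta >= 0 && cfg$align$beta <= 1, "align$beta not in [0,1]")
  chk(cfg$align$alpha >= 0 && cfg$align$alpha <= 1,
      "align$alpha not in [0,1]")
  chk(cfg$align$tau > 0, "align$tau must be > 0")
  chk(cfg$panel$hvg <= cfg$data$n_genes, "panel$hvg exceeds n_genes")
  chk(cfg$panel$target <= cfg$data$n_genes, "panel$target exceeds n_genes")
  chk(cfg$wsi$width >= cfg$wsi$tile_size && cfg$wsi$height >= cfg$wsi$tile_size,
      "wsi dimensions smaller than one tile")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(cfg)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             f)
  unname(tools::md5sum(f))
}

write_manifest <- function(outdir, stage, cfg, inputs, outputs) {
  man <- list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
              inputs = lapply(inputs, function(p)
                list(path = p, md5 = if (file.exists(p))
                  unname(tools::md5sum(p)) else NA)),
              outputs = outputs)
  jsonlite::write_json(man,
                       file.path(outdir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_artifact <- function(path, stage_needed) {
  if (!file.exists(path))
    stop("missing artifact ", path, "; run stage '", stage_needed,
         "' first")
  path
}

pipeline_models <- function(cfg) {
  if (isTRUE(cfg$encoders$tiny)) {
    list(image = tiny_image_config(),
         gene = tiny_gene_config(n_genes = cfg$panel$hvg),
         decoder = tiny_decoder_config(in_dim = 64L,
                                       n_genes_out = cfg$panel$target))
  } else {
    list(image = image_encoder_config(),
         gene = gene_encoder_config(n_genes = cfg$panel$hvg),
         decoder = decoder_config(n_genes_out = cfg$panel$target))
  }
}

#' Run pipeline stages in dependency order
#'
#' @param config a `run_config` from [default_run_config()] (or the same
#'   structure read from YAML)
#' @param stages subset of `simulate`, `preprocess`, `train-align`,
#'   `train-decode`, `predict`, `evaluate`, `wsi`
#' @param outdir output directory for artifacts and manifests
#' @return invisibly, a named list of stage results
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "preprocess", "train-align",
                                    "train-decode", "predict", "evaluate"),
                         outdir = "histex-run") {
  validate_run_config(config)
  order_all <- c("simulate", "preprocess", "train-align", "train-decode",
                 "predict", "evaluate", "wsi")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (st in stages) {
    results[[st]] <- switch(st,
      "simulate" = stage_simulate(config, outdir),
      "preprocess" = stage_preprocess(config, outdir),
      "train-align" = stage_train_align(config, outdir),
      "train-decode" = stage_train_decode(config, outdir),
      "predict" = stage_predict(config, outdir),
      "evaluate" = stage_evaluate(config, outdir),
      "wsi" = stage_wsi(config, outdir))
  }
  invisible(results)
}

slice_spec <- function(cfg, which) {
  synthetic_spec(grid_shape = cfg$data[[paste0(which, "_grid")]],
                 n_genes = cfg$data$n_genes,
                 latent_dim = cfg$data$latent_dim,
                 image_size = cfg$data$image_size,
                 noise_sd = cfg$data$noise_sd,
                 count_depth = cfg$data$count_depth,
                 rng_seed = derive_seed(cfg$seed, paste0("simulate-", which)),
                 loading_seed = cfg$data$loading_seed)
}

stage_simulate <- function(cfg, outdir) {
  for (which in c("train", "val")) {
    g <- generate_slice(slice_spec(cfg, which))
    write_slice(g$slice, file.path(outdir, which))
    utils::write.table(g$latents,
                       file.path(outdir, which, "latents.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  write_manifest(outdir, "simulate", cfg, character(),
                 c("train/", "val/"))
  invisible(TRUE)
}

stage_preprocess <- function(cfg, outdir) {
  tr <- read_slice_dir(require_artifact(file.path(outdir, "train"),
                                        "simulate"))
  norm <- normalize_expression(tr$counts)
  hvg <- select_hvg(norm, tr$gene_names, k = cfg$panel$hvg)
  target <- select_target_genes(norm, tr$gene_names, k = cfg$panel$target)
  writeLines(hvg$names, file.path(outdir, "panel-hvg.tsv"))
  writeLines(target$names, file.path(outdir, "panel-target.tsv"))
  write_manifest(outdir, "preprocess", cfg,
                 file.path(outdir, "train", "counts.mtx"),
                 c("panel-hvg.tsv", "panel-target.tsv"))
  invisible(list(hvg = hvg, target = target))
}

read_panel <- function(outdir, kind) {
  path <- require_artifact(file.path(outdir, paste0("panel-", kind, ".tsv")),
                           "preprocess")
  gene_panel(readLines(path), kind = if (kind == "hvg") "hvg" else "target")
}

stage_train_align <- function(cfg, outdir) {
  tr <- read_slice_dir(require_artifact(file.path(outdir, "train"),
                                        "simulate"))
  hvg <- read_panel(outdir, "hvg")
  mc <- pipeline_models(cfg)
  acfg <- do.call(align_config,
                  c(cfg$align, list(seed = derive_seed(cfg$seed, "align"))))
  model <- alignment_model(mc$image, mc$gene, align_cfg = acfg,
                           seed = derive_seed(cfg$seed, "align-init"))
  model <- train_alignment(model, tr, hvg)
  saveRDS(list(config = model$config, theta = model$theta,
               theta_m = model$theta_m, beta = model$beta,
               step = model$step),
          file.path(outdir, "checkpoint-align.rds"))
  log_path <- file.path(outdir, "train-align-log.jsonl")
  writeLines(vapply(seq_len(nrow(model$log)), function(i)
    jsonlite::toJSON(as.list(model$log[i, ]), auto_unbox = TRUE,
                     digits = NA), character(1)), log_path)
  write_manifest(outdir, "train-align", cfg,
                 file.path(outdir, c("panel-hvg.tsv")),
                 c("checkpoint-align.rds", "train-align-log.jsonl"))
  invisible(model)
}

load_alignment <- function(outdir) {
  ck <- readRDS(require_artifact(file.path(outdir, "checkpoint-align.rds"),
                                 "train-align"))
  structure(c(ck, list(opt = NULL, frozen = FALSE, log = NULL)),
            class = "hx_alignment")
}

encode_training_spots <- function(model, slice, batch = 64L) {
  res <- model$config$image$input_resolution
  enc <- image_branch(model)
  do.call(rbind, lapply(split(seq_len(slice$n),
                              ceiling(seq_len(slice$n) / batch)),
                        function(ix) encode_image(
                          enc, resize_patches(slice$patches[ix], res))))
}

stage_train_decode <- function(cfg, outdir) {
  model <- freeze_encoder(load_alignment(outdir))
  tr <- read_slice_dir(file.path(outdir, "train"))
  target <- read_panel(outdir, "target")
  V <- encode_training_spots(model, tr)
  X <- panel_matrix(normalize_expression(tr$counts), target)
  mc <- pipeline_models(cfg)
  dec <- expression_decoder(mc$decoder, panel = target,
                            seed = derive_seed(cfg$seed, "decode-init"))
  dec <- train_decoder(dec, model, V, X, steps = cfg$decode$steps,
                       batch_size = cfg$decode$batch_size,
                       lr = cfg$decode$lr,
                       seed = derive_seed(cfg$seed, "decode"))
  saveRDS(list(config = dec$config, params = dec$params,
               panel = dec$panel, step = dec$step),
          file.path(outdir, "checkpoint-decode.rds"))
  write_manifest(outdir, "train-decode", cfg,
                 file.path(outdir, c("checkpoint-align.rds",
                                     "panel-target.tsv")),
                 "checkpoint-decode.rds")
  invisible(dec)
}

load_decoder <- function(outdir) {
  ck <- readRDS(require_artifact(file.path(outdir, "checkpoint-decode.rds"),
                                 "train-decode"))
  structure(c(ck, list(opt = NULL, log = NULL)), class = "hx_decoder")
}

stage_predict <- function(cfg, outdir) {
  model <- freeze_encoder(load_alignment(outdir))
  dec <- load_decoder(outdir)
  val <- read_slice_dir(require_artifact(file.path(outdir, "val"),
                                         "simulate"))
  V <- encode_training_spots(model, val)
  Xp <- predict_expression(dec, V)
  utils::write.table(as.data.frame(Xp),
                     file.path(outdir, "predictions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_manifest(outdir, "predict", cfg,
                 file.path(outdir, "checkpoint-decode.rds"),
                 "predictions.tsv")
  invisible(Xp)
}

stage_evaluate <- function(cfg, outdir) {
  model <- load_alignment(outdir)
  val <- read_slice_dir(file.path(outdir, "val"))
  hvg <- read_panel(outdir, "hvg")
  target <- read_panel(outdir, "target")
  emb <- embed_slice(model, val, hvg)
  acc <- list()
  for (k in cfg$eval$adjacent) {
    cs <- lapply(seq_len(val$n), function(q)
      adjacent_candidates(val$coords, q, k))
    acc[[paste0("adjacent", k)]] <- alignment_accuracy(emb$V, emb$E, cs)
  }
  kr <- cfg$eval$random_k
  cs <- lapply(seq_len(val$n), function(q)
    random_candidates(val$n, q, kr,
                      derive_seed(cfg$seed, paste0("rand-cand-", q))))
  acc[[paste0("random", kr)]] <- alignment_accuracy(emb$V, emb$E, cs)

  pred_path <- require_artifact(file.path(outdir, "predictions.tsv"),
                                "predict")
  Xp <- as.matrix(utils::read.delim(pred_path, check.names = FALSE))
  X <- panel_matrix(normalize_expression(val$counts), target)
  rep_ <- evaluate_predictions(X, Xp)
  utils::write.table(
    data.frame(gene = target$names, pcc = rep_$pcc_gene),
    file.path(outdir, "pcc-gene.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(spot = seq_len(val$n), pcc = rep_$pcc_spot),
    file.path(outdir, "pcc-spot.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  report <- c(acc, list(mean_pcc_gene = rep_$mean_pcc_gene,
                        mean_pcc_spot = rep_$mean_pcc_spot,
                        mse = rep_$mse, mae = rep_$mae))
  jsonlite::write_json(report, file.path(outdir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(outdir, "evaluate", cfg,
                 file.path(outdir, c("checkpoint-align.rds",
                                     "predictions.tsv")),
                 c("evaluation.json", "pcc-gene.tsv", "pcc-spot.tsv"))
  invisible(report)
}

stage_wsi <- function(cfg, outdir) {
  model <- freeze_encoder(load_alignment(outdir))
  dec <- load_decoder(outdir)
  fx <- generate_wsi_fixture(cfg$wsi$width, cfg$wsi$height,
                             n_tissue_regions = cfg$wsi$n_tissue_regions,
                             rng_seed = derive_seed(cfg$seed, "wsi"),
                             tile_size = cfg$wsi$tile_size)
  sel <- select_patches(fx$image, tile_size = cfg$wsi$tile_size,
                        n = cfg$wsi$n_tiles)
  utils::write.table(sel$scores, file.path(outdir, "wsi-tile-scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  pred <- predict_wsi(sel$tiles, model, dec)
  utils::write.table(
    data.frame(gene = dec$panel$names %||% seq_along(pred),
               prediction = as.numeric(pred)),
    file.path(outdir, "wsi-prediction.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  write_manifest(outdir, "wsi", cfg,
                 file.path(outdir, c("checkpoint-align.rds",
                                     "checkpoint-decode.rds")),
                 c("wsi-tile-scores.tsv", "wsi-prediction.tsv"))
  invisible(list(scores = sel$scores, prediction = pred))
}
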