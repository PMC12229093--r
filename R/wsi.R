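# Zero-shot whole-slide-image workflow: tile the slide on a non-overlapping
# grid, estimate tissue and nuclei fractions per tile with classical color
# analysis, score tiles as N_t * tanh(T_t), exclude tiles under 60% tissue,
# keep the top 20, predict expression per tile, and average.

#' Estimate tissue and nuclei fractions of a tile
#'
#' Tissue is detected by an HSV saturation threshold (background in an H&E
#' scan is desaturated white); optionally the threshold is chosen by Otsu's
#' method on the saturation histogram. Nuclei are detected by thresholding
#' the hematoxylin concentration obtained from Ruifrok-Johnston color
#' deconvolution with the standard H&E stain vectors.
#'
#' @param tile RGB array, values 0..255
#' @param sat_threshold saturation above which a pixel counts as tissue
#' @param hema_threshold hematoxylin concentration above which a pixel
#'   counts as nuclei
#' @param tissue_method `"fixed"` saturation threshold or `"otsu"`
#' @return named numeric vector `c(T_t, N_t)`, both in `[0, 1]`
#' @export
tissue_nuclei_fractions <- function(tile, sat_threshold = 0.15,
                                    hema_threshold = 0.5,
                                    tissue_method = c("fixed", "otsu")) {
  tissue_method <- match.arg(tissue_method)
  stopifnot(length(dim(tile)) == 3L, dim(tile)[3] >= 3L)
  rgb <- matrix(tile[, , 1:3], ncol = 3L) / 255
  mx <- pmax(rgb[, 1], rgb[, 2], rgb[, 3])
  mn <- pmin(rgb[, 1], rgb[, 2], rgb[, 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  thr <- if (tissue_method == "otsu") otsu_threshold(sat) else sat_threshold
  T_t <- mean(sat > thr)
  # optical density and hematoxylin concentration via deconvolution
  od <- -log10(pmax(rgb, 1 / 255))
  conc <- od %*% he_deconv_matrix()
  N_t <- mean(conc[, 1] > hema_threshold)
  c(T_t = T_t, N_t = N_t)
}

# Ruifrok-Johnston H&E stain vectors (hematoxylin, eosin, residual),
# returned as the OD -> concentration pseudo-inverse
he_deconv_matrix <- function() {
  stains <- rbind(h = c(0.65, 0.70, 0.29),
                  e = c(0.07, 0.99, 0.11),
                  r = c(0.27, 0.57, 0.78))
  stains <- stains / sqrt(rowSums(stains^2))
  solve(stains)
}

otsu_threshold <- function(v, n_breaks = 256L) {
  h <- graphics::hist(v, breaks = seq(0, 1, length.out = n_breaks + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Score a tile from its tissue and nuclei fractions
#'
#' `score = N_t * tanh(T_t)`; tiles with strictly less than 60% tissue are
#' excluded (`T_t = 0.6` is retained).
#'
#' @param T_t tissue fraction in `[0, 1]`
#' @param N_t nuclei fraction in `[0, 1]`
#' @return a one-row data frame with `T_t`, `N_t`, `score`, `excluded`
#' @export
score_patch <- function(T_t, N_t) {
  if (T_t < 0 || T_t > 1 || N_t < 0 || N_t > 1)
    stop("fractions must lie in [0, 1]")
  data.frame(T_t = T_t, N_t = N_t, score = N_t * tanh(T_t),
             excluded = T_t < 0.6)
}

#' Tile a WSI and select the top-scoring patches
#'
#' Tiles the slide on a non-overlapping grid, scores each tile, drops
#' excluded tiles, and returns the `n` highest scores (ties broken by
#' raster order of the tile origin). If fewer than `n` tiles survive the
#' tissue filter, all survivors are returned with a warning.
#'
#' @param wsi RGB array (the level-0 slide raster)
#' @param tile_size tile side length in pixels (default 512)
#' @param n number of tiles to keep (default 20)
#' @param ... passed to [tissue_nuclei_fractions()]
#' @return list with `tiles` (list of RGB arrays) and `scores` (data frame
#'   over all grid tiles, with `selected` flags)
#' @export
select_patches <- function(wsi, tile_size = 512L, n = 20L, ...) {
  h <- dim(wsi)[1]; w <- dim(wsi)[2]
  if (h < tile_size || w < tile_size)
    stop("WSI (", w, "x", h, ") is smaller than one tile (", tile_size, ")")
  xs <- seq(0L, w - tile_size, by = tile_size)
  ys <- seq(0L, h - tile_size, by = tile_size)
  grid <- expand.grid(x = xs, y = ys)
  grid <- grid[order(grid$y, grid$x), , drop = FALSE]   # raster order
  rownames(grid) <- NULL
  frac <- t(mapply(function(x0, y0) {
    tissue_nuclei_fractions(wsi[(y0 + 1):(y0 + tile_size),
                                (x0 + 1):(x0 + tile_size), , drop = FALSE],
                            ...)
  }, grid$x, grid$y))
  scores <- cbind(grid, do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    score_patch(frac[i, "T_t"], frac[i, "N_t"]))))
  keep <- which(!scores$excluded)
  ord <- keep[order(-scores$score[keep], keep)]
  if (length(ord) < n)
    warning("only ", length(ord), " tiles pass the 60% tissue filter ",
            "(requested ", n, ")")
  sel <- ord[seq_len(min(n, length(ord)))]
  scores$selected <- seq_len(nrow(scores)) %in% sel
  tiles <- lapply(sel, function(i)
    wsi[(scores$y[i] + 1):(scores$y[i] + tile_size),
        (scores$x[i] + 1):(scores$x[i] + tile_size), , drop = FALSE])
  list(tiles = tiles, scores = scores)
}

#' Predict a WSI-level expression profile from selected tiles
#'
#' Each tile is resized to the frozen image encoder's input resolution,
#' embedded, and decoded; the elementwise mean over tiles is the slide's
#' predicted expression.
#'
#' @param tiles list of RGB tile arrays
#' @param model a frozen `hx_alignment` providing the image encoder
#' @param decoder a trained `hx_decoder`
#' @return named numeric vector of length `n_genes_out`
#' @export
predict_wsi <- function(tiles, model, decoder) {
  if (!length(tiles)) stop("no tiles to predict from")
  res <- model$config$image$input_resolution
  V <- encode_image(image_branch(model), resize_patches(tiles, res))
  preds <- predict_expression(decoder, V)
  out <- colMeans(preds)
  if (!is.null(decoder$panel)) names(out) <- decoder$panel$names
  out
}
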