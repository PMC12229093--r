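# Seeded synthetic spatial-transcriptomics generator. Each spot carries a
# low-dimensional latent vector shared between its rendered H&E-like patch
# and its Poisson UMI counts, so cross-modal alignment and decoding are
# recoverable and testable without any external data.

#' Specification for a synthetic slice
#'
#' Each spot draws a latent `z ~ N(0, I)` of dimension `latent_dim`. The
#' patch is a deterministic render of `z` (per-quadrant shading, blob
#' amplitudes and color balance are driven by the latent coordinates) plus
#' Gaussian pixel noise; the counts are Poisson with per-gene rates
#' `count_depth * softmax(W z)` for a fixed seeded loading matrix `W` with
#' no gene-specific intercept, so all genes share the same expected depth
#' and spot-to-spot variation carries the signal.
#'
#' @param grid_shape integer (rows, cols); `n_spots = rows * cols`
#' @param n_genes number of genes (default 200)
#' @param latent_dim planted latent dimension (default 4, at most
#'   `min(n_genes, 16)`)
#' @param image_size patch side length in pixels (default 40)
#' @param noise_sd Gaussian pixel noise standard deviation on the 0..255
#'   scale (default 8)
#' @param count_depth expected total UMI per spot (default 10000)
#' @param rng_seed integer seed making the slice fully reproducible
#' @param loading_seed seed for the gene loading matrix `W`; slices that
#'   share `loading_seed` share the planted image-to-expression mapping,
#'   so models trained on one slice transfer to another
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(grid_shape = c(8L, 8L), n_genes = 200L,
                           latent_dim = 4L, image_size = 40L,
                           noise_sd = 8, count_depth = 10000,
                           rng_seed = 1L, loading_seed = 42L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L),
            n_genes >= 2L, latent_dim >= 1L,
            latent_dim <= min(n_genes, 16L),
            image_size >= 8L, noise_sd >= 0, count_depth > 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_spots = as.integer(prod(grid_shape)),
                 n_genes = as.integer(n_genes),
                 latent_dim = as.integer(latent_dim),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, count_depth = count_depth,
                 rng_seed = as.integer(rng_seed),
                 loading_seed = as.integer(loading_seed)),
            class = "synthetic_spec")
}

# Deterministic patch render: the first four latent coordinates set the
# brightness and blob amplitude of the four quadrants; fixed per-quadrant
# channel weights give each quadrant a distinct hue.
render_patch <- function(z, image_size) {
  s <- image_size
  half <- s %/% 2L
  zq <- rep_len(z, 4L)
  base <- 0.45 + 0.3 * tanh(zq / 1.5)
  colw <- matrix(c(1.00, 0.75, 0.85,
                   0.80, 1.00, 0.70,
                   0.70, 0.85, 1.00,
                   0.90, 0.90, 0.75), 3L, 4L)
  img <- array(0, c(s, s, 3L))
  qrows <- list(1:half, 1:half, (half + 1L):s, (half + 1L):s)
  qcols <- list(1:half, (half + 1L):s, 1:half, (half + 1L):s)
  gx <- outer(rep(1, half), seq_len(s - half + (s %% 2L)))
  for (q in 1:4) {
    rr <- qrows[[q]]; cc <- qcols[[q]]
    yy <- matrix(rep(seq_along(rr), length(cc)), length(rr))
    xx <- matrix(rep(seq_along(cc), each = length(rr)), length(rr))
    cy <- (length(rr) + 1) / 2; cx <- (length(cc) + 1) / 2
    blob <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * (s / 8)^2))
    amp <- 0.25 * tanh(zq[q])
    for (ch in 1:3)
      img[rr, cc, ch] <- 255 * pmin(pmax(
        base[q] * colw[ch, q] + amp * blob, 0), 1)
  }
  img
}

#' Generate a synthetic slice with planted cross-modal structure
#'
#' @param spec a [synthetic_spec()]
#' @return list with `slice` (a `spot_slice`), `latents` (spots x
#'   latent_dim matrix) and `loadings` (genes x latent_dim matrix `W`)
#' @export
generate_slice <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_spots
    Z <- matrix(stats::rnorm(n * spec$latent_dim), n, spec$latent_dim)
    W <- with_seed(spec$loading_seed,
                   matrix(stats::rnorm(spec$n_genes * spec$latent_dim,
                                       sd = 0.75),
                          spec$n_genes, spec$latent_dim))
    logits <- Z %*% t(W)
    probs <- exp(logits - apply(logits, 1L, max))
    probs <- probs / rowSums(probs)
    counts <- matrix(stats::rpois(n * spec$n_genes,
                                  lambda = spec$count_depth * probs),
                     n, spec$n_genes)
    patches <- lapply(seq_len(n), function(i) {
      img <- render_patch(Z[i, ], spec$image_size)
      if (spec$noise_sd > 0)
        img <- clamp255(img + array(stats::rnorm(length(img),
                                                 sd = spec$noise_sd),
                                    dim = dim(img)))
      img
    })
    rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
    coords <- cbind(x = rep(seq_len(cols) - 1L, each = rows),
                    y = rep(seq_len(rows) - 1L, cols))
    gene_names <- sprintf("gene-%04d", seq_len(spec$n_genes))
    slice <- spot_slice(sprintf("synthetic-seed%d", spec$rng_seed),
                        patches, counts, gene_names, coords)
    list(slice = slice, latents = Z, loadings = W)
  })
}

#' Generate a synthetic whole-slide image with known tile fractions
#'
#' Paints elliptical tissue regions in an eosin-like stain and nuclei dots
#' in a hematoxylin-like stain on a white background. Colors follow the
#' Beer-Lambert law with known stain concentrations, so the classical
#' deconvolution-based estimators are exercised against exact per-tile
#' ground truth.
#'
#' @param width,height image dimensions in pixels
#' @param n_tissue_regions number of elliptical tissue regions
#' @param rng_seed integer seed
#' @param tile_size tile side used for the ground-truth table (default 512)
#' @param noise_sd pixel noise on the 0..255 scale (default 2)
#' @return list with `image` (height x width x 3), `tiles` (data frame of
#'   tile origins and true tissue/nuclei fractions `T_t`, `N_t`) and the
#'   binary `tissue_mask` / `nuclei_mask`
#' @export
generate_wsi_fixture <- function(width, height, n_tissue_regions = 4L,
                                 rng_seed = 1L, tile_size = 512L,
                                 noise_sd = 2) {
  stopifnot(width >= tile_size, height >= tile_size)
  with_seed(rng_seed, {
    tissue <- matrix(FALSE, height, width)
    yy <- matrix(rep(seq_len(height), width), height)
    xx <- matrix(rep(seq_len(width), each = height), height)
    for (k in seq_len(n_tissue_regions)) {
      cx <- stats::runif(1, 0.15, 0.85) * width
      cy <- stats::runif(1, 0.15, 0.85) * height
      rx <- stats::runif(1, 0.12, 0.3) * width
      ry <- stats::runif(1, 0.12, 0.3) * height
      tissue <- tissue | (((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1)
    }
    nuclei <- matrix(FALSE, height, width)
    idx_tissue <- which(tissue)
    if (length(idx_tissue)) {
      n_nuc <- max(1L, round(length(idx_tissue) / 900))
      centers <- sample(idx_tissue, n_nuc)
      cys <- (centers - 1L) %% height + 1L
      cxs <- (centers - 1L) %/% height + 1L
      r <- 6L
      for (k in seq_along(centers)) {
        r0 <- max(1L, cys[k] - r):min(height, cys[k] + r)
        c0 <- max(1L, cxs[k] - r):min(width, cxs[k] + r)
        sub <- outer((r0 - cys[k])^2, (c0 - cxs[k])^2, "+") <= r^2
        nuclei[r0, c0] <- nuclei[r0, c0] | sub
      }
      nuclei <- nuclei & tissue
    }
    # Beer-Lambert rendering with standard H&E stain vectors
    od_h <- c(0.65, 0.70, 0.29)
    od_e <- c(0.07, 0.99, 0.11)
    conc_h <- ifelse(nuclei, 1.0, 0)
    conc_e <- ifelse(tissue & !nuclei, 0.5, ifelse(nuclei, 0.1, 0))
    img <- array(0, c(height, width, 3L))
    for (ch in 1:3)
      img[, , ch] <- 255 * 10^(-(conc_h * od_h[ch] + conc_e * od_e[ch]))
    if (noise_sd > 0)
      img <- clamp255(img + array(stats::rnorm(length(img), sd = noise_sd),
                                  dim = dim(img)))
    tx <- seq(0L, width - tile_size, by = tile_size)
    ty <- seq(0L, height - tile_size, by = tile_size)
    tiles <- expand.grid(x = tx, y = ty)
    tiles <- tiles[order(tiles$y, tiles$x), , drop = FALSE]
    tiles$T_t <- mapply(function(x0, y0)
      mean(tissue[(y0 + 1):(y0 + tile_size), (x0 + 1):(x0 + tile_size)]),
      tiles$x, tiles$y)
    tiles$N_t <- mapply(function(x0, y0)
      mean(nuclei[(y0 + 1):(y0 + tile_size), (x0 + 1):(x0 + tile_size)]),
      tiles$x, tiles$y)
    rownames(tiles) <- NULL
    list(image = img, tiles = tiles, tissue_mask = tissue,
         nuclei_mask = nuclei)
  })
}
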