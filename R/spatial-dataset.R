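# Spot-level spatial transcriptomics data model and preprocessing:
# center-cropped H&E patches, CPM log normalization, highly variable and
# high-expression gene panels, and seeded patch augmentation.

#' Construct a spot-level slice
#'
#' Bundles one tissue slice's paired data: an H&E patch, a UMI count vector
#' and an (x, y) coordinate per spot. Coordinates are pixel-space centers,
#' 0-based, ordered (x = column, y = row).
#'
#' @param slice_id character identifier
#' @param patches list of RGB rasters (height x width x 3 arrays, 0..255)
#' @param counts spots x genes matrix of non-negative integer UMI counts
#' @param gene_names character vector, one unique name per counts column
#' @param coords spots x 2 numeric matrix of (x, y) spot centers
#' @return an object of class `spot_slice`
#' @export
spot_slice <- function(slice_id, patches, counts, gene_names, coords) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  n <- nrow(counts)
  if (length(patches) != n)
    stop("patches (", length(patches), ") and counts rows (", n, ") differ")
  if (nrow(coords) != n)
    stop("coords rows (", nrow(coords), ") and counts rows (", n, ") differ")
  if (ncol(coords) != 2L) stop("coords must have 2 columns")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(gene_names) != ncol(counts))
    stop("gene_names length (", length(gene_names),
         ") and counts columns (", ncol(counts), ") differ")
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  colnames(counts) <- gene_names
  colnames(coords) <- c("x", "y")
  structure(list(slice_id = slice_id, patches = patches, counts = counts,
                 gene_names = gene_names, coords = coords, n = n),
            class = "spot_slice")
}

#' @export
print.spot_slice <- function(x, ...) {
  ps <- if (x$n > 0) paste(dim(x$patches[[1]])[1:2], collapse = "x") else "-"
  cat("<spot_slice> ", x$slice_id, ": ", x$n, " spots, ",
      ncol(x$counts), " genes, patches ", ps, "\n", sep = "")
  invisible(x)
}

#' Construct a gene panel
#'
#' @param names ordered character vector of unique gene identifiers
#' @param kind `"hvg"` (encoder input panel) or `"target"` (decoder output
#'   panel)
#' @return an object of class `gene_panel`
#' @export
gene_panel <- function(names, kind = c("hvg", "target")) {
  kind <- match.arg(kind)
  if (anyDuplicated(names)) stop("panel gene names must be unique")
  structure(list(names = as.character(names), kind = kind,
                 size = length(names)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$kind, ", ", x$size, " genes\n", sep = "")
  invisible(x)
}

#' Center-crop a square window from an RGB raster
#'
#' The output pixel at the crop center equals the input pixel at `center`.
#' Windows overhanging the image border are zero-padded so every spot keeps
#' a patch of the requested size.
#'
#' @param image RGB array height x width x 3
#' @param center numeric (x, y), 0-based pixel coordinates; must lie inside
#'   the image
#' @param size crop side length in pixels
#' @return size x size x 3 array
#' @export
center_crop <- function(image, center, size) {
  stopifnot(size > 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  cx <- round(center[1]); cy <- round(center[2])
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    stop("crop center (", center[1], ", ", center[2], ") outside image ",
         w, "x", h)
  half <- size %/% 2L
  r0 <- cy - half; c0 <- cx - half          # 0-based top-left of the window
  out <- array(0, c(size, size, dim(image)[3]))
  rr <- max(r0, 0):min(r0 + size - 1L, h - 1L)
  cc <- max(c0, 0):min(c0 + size - 1L, w - 1L)
  out[rr - r0 + 1L, cc - c0 + 1L, ] <- image[rr + 1L, cc + 1L, , drop = FALSE]
  out
}

#' CPM log normalization of UMI counts
#'
#' Scales each spot to one million total counts and applies `log(1 + .)`,
#' so zeros stay zero and within-spot rank order is preserved.
#'
#' @param counts spots x genes non-negative matrix
#' @return spots x genes matrix of `log(1 + CPM)` values
#' @export
normalize_expression <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  bad <- which(tot <= 0)
  if (length(bad))
    stop("spot(s) with zero total counts: ", paste(bad, collapse = ", "))
  log1p(counts / tot * 1e6)
}

rank_genes <- function(score, gene_names, k, label) {
  if (k > length(gene_names))
    stop("k (", k, ") exceeds number of genes (", length(gene_names), ")")
  ord <- order(-score, gene_names)
  gene_names[ord[seq_len(k)]]
}

#' Select the highly variable gene panel
#'
#' Genes are ranked by dispersion (variance / mean of the normalized values,
#' zero when a gene is all-zero); ties break by gene-name order so the panel
#' is deterministic and permutation-invariant.
#'
#' @param normalized spots x genes matrix from [normalize_expression()]
#' @param gene_names character vector naming the columns
#' @param k panel size (default 2000)
#' @return a `gene_panel` of kind `"hvg"`
#' @export
select_hvg <- function(normalized, gene_names, k = 2000L) {
  mu <- colMeans(normalized)
  v <- apply(normalized, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  gene_panel(rank_genes(disp, gene_names, k, "hvg"), kind = "hvg")
}

#' Select the high-expression target gene panel
#'
#' Genes are ranked by mean normalized expression across all training spots;
#' ties break by gene-name order.
#'
#' @inheritParams select_hvg
#' @param k panel size (default 300)
#' @return a `gene_panel` of kind `"target"`
#' @export
select_target_genes <- function(normalized, gene_names, k = 300L) {
  gene_panel(rank_genes(colMeans(normalized), gene_names, k, "target"),
             kind = "target")
}

#' Seeded photometric/geometric patch augmentation
#'
#' Applies, in order: random crop-and-resize, horizontal and vertical flips
#' (each with probability `flip_prob`), contrast jitter about the patch mean,
#' and additive brightness jitter, then clamps to 0..255. The output is fully
#' determined by `rng_seed`.
#'
#' @param patch RGB array, values 0..255
#' @param rng_seed integer seed
#' @param scale_range crop area scale range as a fraction of the side length
#' @param flip_prob probability of each flip
#' @param brightness max absolute brightness shift as a fraction of 255
#' @param contrast max relative contrast change
#' @return augmented patch, same dimensions
#' @export
augment_patch <- function(patch, rng_seed, scale_range = c(0.8, 1),
                          flip_prob = 0.5, brightness = 0.1, contrast = 0.1) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  with_seed(rng_seed, {
    s <- stats::runif(1, scale_range[1], scale_range[2])
    ch <- max(1L, round(h * s)); cw <- max(1L, round(w * s))
    r0 <- if (h > ch) sample.int(h - ch + 1L, 1L) else 1L
    c0 <- if (w > cw) sample.int(w - cw + 1L, 1L) else 1L
    out <- patch[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), , drop = FALSE]
    out <- resize_bilinear(out, h, w)
    if (stats::runif(1) < flip_prob) out <- out[, w:1, , drop = FALSE]
    if (stats::runif(1) < flip_prob) out <- out[h:1, , , drop = FALSE]
    if (contrast > 0) {
      f <- 1 + stats::runif(1, -contrast, contrast)
      m <- mean(out)
      out <- (out - m) * f + m
    }
    if (brightness > 0)
      out <- out + stats::runif(1, -brightness, brightness) * 255
    clamp255(out)
  })
}

## ---- directory serialization ----

#' Load a slice from counts, gene, coordinate and image files
#'
#' Counts are read from MatrixMarket (`.mtx`, stored genes x spots) or a
#' delimited spots x genes table. `image_source` is either a single image
#' whose coordinates index patch centers (patches are center-cropped, with
#' zero padding at the border), or a directory of per-spot patch images
#' written by [write_slice()].
#'
#' @param counts_path path to `.mtx` or delimited counts
#' @param genes_path one gene name per line
#' @param coords_path delimited table with columns x, y (optionally barcode)
#' @param image_source image file or `patches/` directory
#' @param patch_size crop side length in pixels (default 40)
#' @param slice_id identifier for the slice
#' @return a `spot_slice`
#' @export
load_slice <- function(counts_path, genes_path, coords_path, image_source,
                       patch_size = 40L, slice_id = "slice") {
  for (p in c(counts_path, genes_path, coords_path, image_source))
    if (!file.exists(p)) stop("file not found: ", p)
  gene_names <- readLines(genes_path)
  gene_names <- gene_names[nzchar(gene_names)]
  counts <- read_counts(counts_path, length(gene_names))
  if (ncol(counts) != length(gene_names))
    stop("counts columns (", ncol(counts), ") do not match gene list ",
         basename(genes_path), " (", length(gene_names), ")")
  coords <- utils::read.delim(coords_path, header = TRUE)
  xy <- as.matrix(coords[, intersect(c("x", "y"), names(coords)), drop = FALSE])
  if (ncol(xy) != 2L)
    xy <- as.matrix(coords[, vapply(coords, is.numeric, TRUE), drop = FALSE][, 1:2])
  if (nrow(xy) != nrow(counts))
    stop("barcode count mismatch: ", basename(coords_path), " has ",
         nrow(xy), " rows but counts have ", nrow(counts), " spots")
  patches <- if (dir.exists(image_source)) {
    files <- sort(list.files(image_source, pattern = "\\.png$",
                             full.names = TRUE))
    if (length(files) != nrow(counts))
      stop("barcode count mismatch: ", image_source, " holds ",
           length(files), " patches but counts have ", nrow(counts), " spots")
    lapply(files, read_image)
  } else {
    img <- read_image(image_source)
    h <- dim(img)[1]; w <- dim(img)[2]
    out <- which(xy[, 1] < 0 | xy[, 1] > w - 1 | xy[, 2] < 0 | xy[, 2] > h - 1)
    if (length(out))
      stop("coordinates outside image bounds for spot(s): ",
           paste(out, collapse = ", "))
    lapply(seq_len(nrow(xy)), function(i)
      center_crop(img, xy[i, ], patch_size))
  }
  spot_slice(slice_id, patches, counts, gene_names, xy)
}

read_counts <- function(path, n_genes) {
  if (tolower(tools::file_ext(path)) == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    # stored genes x spots (matrix-market convention); orient spots x genes
    if (nrow(m) == n_genes) t(m) else m
  } else {
    as.matrix(utils::read.delim(path, header = FALSE))
  }
}

#' Serialize a slice to the on-disk directory layout
#'
#' Writes `counts.mtx` (genes x spots), `genes.tsv`, `barcodes.tsv`,
#' `coords.tsv`, `patches/NNNN.png` and a JSON `manifest.json`.
#'
#' @param slice a `spot_slice`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_slice <- function(slice, dir) {
  dir.create(file.path(dir, "patches"), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(t(slice$counts), sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(slice$gene_names, file.path(dir, "genes.tsv"))
  writeLines(sprintf("spot-%04d", seq_len(slice$n)),
             file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = sprintf("spot-%04d", seq_len(slice$n)),
               x = slice$coords[, 1], y = slice$coords[, 2]),
    file.path(dir, "coords.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  for (i in seq_len(slice$n))
    write_image(slice$patches[[i]],
                file.path(dir, "patches", sprintf("%04d.png", i)))
  manifest <- list(slice_id = slice$slice_id, n = slice$n,
                   n_genes = ncol(slice$counts),
                   patch_size = dim(slice$patches[[1]])[1],
                   files = c("counts.mtx", "genes.tsv", "barcodes.tsv",
                             "coords.tsv", "patches/"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a slice from a directory written by [write_slice()]
#'
#' @param dir directory containing the serialized slice
#' @return a `spot_slice`
#' @export
read_slice_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  load_slice(file.path(dir, "counts.mtx"), file.path(dir, "genes.tsv"),
             file.path(dir, "coords.tsv"), file.path(dir, "patches"),
             slice_id = manifest$slice_id %||% basename(dir))
}

#' Restrict a slice's expression matrix to a gene panel
#'
#' @param normalized spots x genes matrix with column names
#' @param panel a `gene_panel`
#' @return spots x panel-size matrix in panel order
#' @export
panel_matrix <- function(normalized, panel) {
  missing <- setdiff(panel$names, colnames(normalized))
  if (length(missing))
    stop("genes absent from matrix: ", paste(utils::head(missing, 5),
                                             collapse = ", "))
  normalized[, panel$names, drop = FALSE]
}
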