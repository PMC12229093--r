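# Image helpers shared across modules. Images are numeric arrays
# height x width x 3 with values on the 0..255 scale.

#' Read an RGB image from PNG or TIFF
#'
#' @param path image file path
#' @return numeric array height x width x 3, values in 0..255
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB image to PNG
#'
#' @param img numeric array height x width x 3, values in 0..255
#' @param path output path
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Bilinear resize of an RGB raster
#'
#' Resizing to the input dimensions is an exact identity.
#'
#' @param img numeric array height x width x channels
#' @param out_h,out_w output dimensions in pixels
#' @return resized array
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]; nc <- if (length(d) == 3L) d[3] else 1L
  if (h == out_h && w == out_w) return(img)
  if (length(d) == 2L) img <- array(img, c(h, w, 1L))
  # map output pixel centers onto input pixel centers
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, nc))
  for (cc in seq_len(nc)) {
    ch <- img[, , cc]
    a <- ch[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
    b <- ch[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
    cpx <- ch[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
    dpx <- ch[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
    fyg <- rep(fy, out_w); fxg <- rep(fx, each = out_h)
    vals <- a * (1 - fyg) * (1 - fxg) + b * (1 - fyg) * fxg +
      cpx * fyg * (1 - fxg) + dpx * fyg * fxg
    out[, , cc] <- matrix(vals, out_h, out_w)
  }
  if (length(d) == 2L) out <- out[, , 1L]
  out
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

`%||%` <- function(a, b) if (is.null(a)) b else a
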