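#' Read an RGB image
#'
#' Reads an 8-bit-per-channel PNG or TIFF file into a `height x width x 3`
#' numeric array with intensities on the 0--255 scale (row-major, 0-based
#' pixel convention in all coordinate-facing interfaces).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `h x w x 3` in `[0, 255]`.
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB or grayscale image as 8-bit PNG
#'
#' @param img Matrix (grayscale) or `h x w x 3` array on the 0--255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  img <- pmin(pmax(img / 255, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Write an integer label mask as a grayscale PNG
#'
#' Cell labels are stored as 8-bit gray values (one level per cell id).
#' The `png` writer available here is 8-bit only, so masks with more than
#' 255 cells are refused; smear fields analysed by this package are far
#' below that.
#'
#' @param label_mask Integer matrix, 0 = background, k = cell index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(label_mask, path) {
  m <- max(label_mask)
  if (m > 255) stop("label mask has ", m, " labels; 8-bit PNG supports at most 255")
  png::writePNG(label_mask / 255, path)
  invisible(path)
}

## ---- internal raster helpers ------------------------------------------------

# replicate-pad a matrix by `p` pixels on every side
pad_replicate <- function(m, p) {
  if (p <= 0) return(m)
  ri <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}

# reflect-pad (mirror without repeating the edge pixel when possible)
pad_reflect <- function(m, p) {
  if (p <= 0) return(m)
  refl <- function(n, p) {
    idx <- seq_len(n)
    top <- rev(seq_len(min(p, n - 1)) + 1L)
    if (length(top) < p) top <- c(rep(1L, p - length(top)), top)
    bot <- n - seq_len(min(p, n - 1))
    if (length(bot) < p) bot <- c(bot, rep(n, p - length(bot)))
    c(top, idx, bot)
  }
  m[refl(nrow(m), p), refl(ncol(m), p), drop = FALSE]
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# rounding with the half-away-from-zero tie rule (R's round() is banker's)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 2D linear convolution via FFT, "same" output size (centered), complex kernels
# supported.  Kernel FFTs are cached per (kernel id, padded size) because the
# Gabor bank reuses the same kernels across hundreds of cell crops.
.fft_cache <- new.env(parent = emptyenv())

fft_convolve_same <- function(x, kern, kern_id = NULL) {
  nr <- nrow(x) + nrow(kern) - 1L
  nc <- ncol(x) + ncol(kern) - 1L
  NR <- stats::nextn(nr, c(2, 3, 5))
  NC <- stats::nextn(nc, c(2, 3, 5))
  xp <- matrix(0 + 0i, NR, NC)
  xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  FX <- stats::fft(xp)
  key <- if (is.null(kern_id)) NULL else paste(kern_id, NR, NC, sep = "_")
  FK <- if (!is.null(key) && !is.null(.fft_cache[[key]])) {
    .fft_cache[[key]]
  } else {
    kp <- matrix(0 + 0i, NR, NC)
    kp[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
    fk <- stats::fft(kp)
    if (!is.null(key)) .fft_cache[[key]] <- fk
    fk
  }
  full <- stats::fft(FX * FK, inverse = TRUE) / (NR * NC)
  # "same" block: centre of the full convolution aligned with x
  r0 <- (nrow(kern) - 1L) %/% 2L
  c0 <- (ncol(kern) - 1L) %/% 2L
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
}

# rasterize an anti-aliased disk: coverage in [0,1] per pixel of an
# nr x nc frame, disk centred at (r0, c0) (1-based, may be fractional)
disk_coverage <- function(nr, nc, r0, c0, radius, soft = 0.7) {
  rows <- max(1L, floor(r0 - radius - 2)):min(nr, ceiling(r0 + radius + 2))
  cols <- max(1L, floor(c0 - radius - 2)):min(nc, ceiling(c0 + radius + 2))
  d <- sqrt(outer((rows - r0)^2, (cols - c0)^2, "+"))
  cov <- pmin(pmax((radius + soft / 2 - d) / soft, 0), 1)
  list(rows = rows, cols = cols, cov = cov)
}

is_binary_mask <- function(m) is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
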