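#' Select the green channel of an RGB smear
#'
#' Stain absorbs green most strongly, so the green channel carries the best
#' cell/background contrast in Romanowsky-stained smears.
#'
#' @param rgb_image `h x w x 3` array (R, G, B order).
#' @return Numeric matrix (the green channel, unchanged).
#' @export
select_green_channel <- function(rgb_image) {
  d <- dim(rgb_image)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected a 3-channel RGB array, got dimensions: ",
         paste(d, collapse = " x "))
  rgb_image[, , 2]
}

#' Balance contrast enhancement (BCET)
#'
#' Parabolic intensity mapping `y = a (x - b)^2 + c` with coefficients solved
#' in closed form from the input minimum, maximum, mean and mean of squares so
#' that the output hits `out_min`, `out_max` and (in expectation, before
#' clipping) `out_mean` exactly.
#'
#' With `out_mean = NULL` the target mean is placed where a plain linear
#' stretch would put it; this keeps the parabola's vertex outside the input
#' range, hence the mapping monotone, which matters when the input histogram
#' is dominated by a bright background (the fixed mid-gray target would fold
#' dark and mid intensities together).
#'
#' @param image Numeric matrix of intensities.
#' @param out_min,out_max,out_mean Output anchors; `out_mean = NULL` picks the
#'   monotone (linear-stretch) target.
#' @return Enhanced matrix, clipped to `[out_min, out_max]`.
#' @export
bcet_enhance <- function(image, out_min = 0, out_max = 255, out_mean = 128) {
  if (out_min >= out_max) stop("out_min must be < out_max")
  l <- min(image); h <- max(image)
  if (h <= l) {
    warning("constant image: no contrast to balance; returning input unchanged")
    return(image)
  }
  e <- mean(image)
  s <- mean(image^2)
  L <- out_min; H <- out_max
  E <- if (is.null(out_mean)) L + (e - l) / (h - l) * (H - L) else out_mean
  den <- 2 * (h * (E - L) - e * (H - L) + l * (H - E))
  linear <- function() pmin(pmax((image - l) / (h - l) * (H - L) + L, L), H)
  # the anchor system can be inconsistent (e.g. a two-level image whose
  # stretched mean cannot equal E); both degeneracies fall back to the
  # linear stretch, which still meets the min/max anchors
  if (abs(den) < 1e-9 * (H - L) * (h - l)) return(linear())
  b <- (h^2 * (E - L) - s * (H - L) + l^2 * (H - E)) / den
  if (abs(h + l - 2 * b) < 1e-9 * (h - l)) return(linear())
  a <- (H - L) / ((h - l) * (h + l - 2 * b))
  cc <- L - a * (l - b)^2
  out <- a * (image - b)^2 + cc
  pmin(pmax(out, L), H)
}

#' Median smoothing with edge replication
#'
#' @param image Numeric matrix on the 0--255 scale.
#' @param window Odd window size (default 3).
#' @return Smoothed matrix.
#' @export
median_smooth <- function(image, window = 3) {
  if (window %% 2 != 1 || window < 1) stop("window must be an odd integer >= 1")
  if (window == 1) return(image)
  r <- (window - 1L) %/% 2L
  pad <- pad_replicate(image, r)
  sm <- EBImage::medianFilter(pad / 255, size = r) * 255
  sm <- as.matrix(sm)
  sm[r + seq_len(nrow(image)), r + seq_len(ncol(image)), drop = FALSE]
}

#' Quantize an image with its mean intensity as the step
#'
#' The scale factor is the image mean `Fg`; every pixel is snapped to the
#' nearest multiple of `Fg`, ties rounding half away from zero.  In a smear
#' field this collapses background and red cells onto the same level while
#' the much darker WBC nuclei fall to level zero, which is what makes the
#' downstream XOR removal of WBCs possible.
#'
#' @param image Numeric matrix.
#' @return List of class `"quantized_image"` with `pixels` (real-valued
#'   multiples of `scale_factor`) and `scale_factor` (`Fg`).
#' @export
quantize_mean_step <- function(image) {
  if (length(image) == 0) stop("empty image")
  fg <- mean(image)
  pixels <- if (fg == 0) image * 0 else fg * round_half_away(image / fg)
  structure(list(pixels = pixels, scale_factor = fg), class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat("Quantized image", paste(dim(x$pixels), collapse = " x "),
      "- scale factor Fg =", format(x$scale_factor, digits = 5), "\n")
  invisible(x)
}

#' Full preprocessing of an RGB smear
#'
#' Green channel -> BCET contrast balance -> median smoothing -> mean-step
#' quantization, returning both the enhanced gray image and its quantized
#' companion (the two inputs of the two-step binarization).
#'
#' @param rgb_image `h x w x 3` array, 0--255.
#' @param bcet_mean Target mean for BCET; the pipeline default `NULL` keeps
#'   the mapping monotone (see [bcet_enhance()]).
#' @param median_window Odd median window (default 3).
#' @return List with `gray` (enhanced, smoothed green channel) and
#'   `quantized` (a `"quantized_image"`).
#' @export
preprocess_smear <- function(rgb_image, bcet_mean = NULL, median_window = 3) {
  g <- select_green_channel(rgb_image)
  g <- bcet_enhance(g, out_mean = bcet_mean)
  g <- median_smooth(g, median_window)
  list(gray = g, quantized = quantize_mean_step(g))
}
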