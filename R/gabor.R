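## Gabor filter bank: oriented complex band-pass filters (2D Fourier carrier
## under an origin-centred Gaussian envelope) applied per cell, summarized by
## mean amplitude and mean squared energy of the masked response.

#' Construct a Gabor filter bank
#'
#' One complex kernel per (wavelength, orientation) pair.  Each kernel is a
#' complex exponential of frequency `f = 1/wavelength` along the rotated
#' x-axis under an isotropic Gaussian envelope with `sigma =
#' sigma_factor * wavelength` (the default 0.56 corresponds to a one-octave
#' half-response bandwidth).  Support is truncated at 3 sigma and the
#' envelope-weighted mean is subtracted, so every kernel sums to (numerically)
#' zero and constant image regions give zero response.
#'
#' Instead of explicit wavelengths, a geometric frequency ladder can be
#' requested via `fmax`, `k` and `M` (frequencies `fmax * k^-m`,
#' `m = 0..M-1`); the explicit wavelength list is the default mode.
#'
#' @param wavelengths Pixels per cycle, ascending (default `c(3, 6, 9, 12)`).
#' @param orientations Degrees in `[0, 180)` (default `c(30, 60, 90)`).
#' @param sigma_factor Envelope sigma as a multiple of wavelength.
#' @param fmax,k,M Optional geometric frequency ladder (overrides
#'   `wavelengths` when all three are given).
#' @return List of class `"gabor_bank"`; each element has `kernel` (complex
#'   matrix), `wavelength`, `orientation`, `id`.  Ordering is
#'   wavelength-major (wavelength varies slowest).
#' @export
gabor_bank <- function(wavelengths = c(3, 6, 9, 12),
                       orientations = c(30, 60, 90),
                       sigma_factor = 0.56,
                       fmax = NULL, k = NULL, M = NULL) {
  if (!is.null(fmax) && !is.null(k) && !is.null(M)) {
    stopifnot(fmax > 0, fmax <= 0.5, k > 1, M >= 1)
    wavelengths <- 1 / (fmax * k^-(seq_len(M) - 1))
  }
  stopifnot(length(wavelengths) >= 1, length(orientations) >= 1,
            all(diff(wavelengths) > 0) || length(wavelengths) == 1)
  if (any(wavelengths < 2))
    stop("wavelength below 2 px would alias on the pixel lattice")
  if (any(orientations < 0 | orientations >= 180))
    stop("orientations must lie in [0, 180) degrees")
  bank <- list()
  for (lam in wavelengths) {
    f <- 1 / lam
    sigma <- sigma_factor * lam
    half <- ceiling(3 * sigma)
    xs <- -half:half
    for (th in orientations) {
      t <- th * pi / 180
      # x' along the carrier; coordinates (row, col) = (y down, x right)
      xp <- outer(-xs * sin(t), xs * cos(t), "+")
      rr <- outer(xs^2, xs^2, "+")
      env <- exp(-rr / (2 * sigma^2))
      kern <- (f^2 / (2 * pi * sigma_factor^2)) * env * exp(2i * pi * f * xp)
      kern <- kern - env * (sum(kern) / sum(env))  # remove DC, keep locality
      bank[[length(bank) + 1L]] <- list(kernel = kern, wavelength = lam,
                                        orientation = th,
                                        id = sprintf("w%g_o%g", lam, th))
    }
  }
  structure(bank, class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("Gabor bank:", length(x), "filters;",
      "wavelengths", paste(unique(vapply(x, `[[`, 0, "wavelength")), collapse = ", "),
      "px; orientations",
      paste(unique(vapply(x, `[[`, 0, "orientation")), collapse = ", "), "deg\n")
  invisible(x)
}

#' Gabor features of a cell crop
#'
#' Convolves each complex kernel with the gray crop (reflect padding so the
#' response is defined up to the crop border) and summarizes the response
#' magnitude over the mask pixels: mean squared energy `MSE = mean(|r|^2)`
#' and mean amplitude `MA = mean(|r|)` per filter.  With the default
#' 12-filter bank this yields 24 values, the MSE block followed by the MA
#' block, in the bank's wavelength-major order.
#'
#' @param gray_crop Numeric matrix (enhanced gray intensities).
#' @param mask Logical matrix, same shape.
#' @param bank A [gabor_bank()].
#' @return Named numeric vector, `gabor_mse_*` then `gabor_ma_*`.
#' @export
extract_gabor <- function(gray_crop, mask, bank = gabor_bank()) {
  stopifnot(inherits(bank, "gabor_bank"), all(dim(gray_crop) == dim(mask)))
  if (!any(mask)) stop("empty mask")
  halfmax <- max(vapply(bank, function(b) (nrow(b$kernel) - 1L) %/% 2L, 0L))
  padded <- pad_reflect(gray_crop, halfmax)
  sel <- which(rbind(matrix(FALSE, halfmax, ncol(padded)),
                     cbind(matrix(FALSE, nrow(mask), halfmax), mask,
                           matrix(FALSE, nrow(mask), halfmax)),
                     matrix(FALSE, halfmax, ncol(padded))))
  mse <- ma <- numeric(length(bank))
  for (i in seq_along(bank)) {
    resp <- fft_convolve_same(padded, bank[[i]]$kernel, kern_id = bank[[i]]$id)
    mag <- Mod(resp[sel])
    mse[i] <- mean(mag^2)
    ma[i] <- mean(mag)
  }
  ids <- vapply(bank, `[[`, "", "id")
  stats::setNames(c(mse, ma), c(paste0("gabor_mse_", ids), paste0("gabor_ma_", ids)))
}
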