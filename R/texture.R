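## Intensity and matrix-based texture features of one cell: RGB statistics,
## gray-level co-occurrence matrix (GLCM) features and gray-level run-length
## matrix (GLRLM) features, each angle-averaged over 0, 45, 90 and 135 degrees.

#' Per-channel colour statistics of a cell
#'
#' Means and population variances (divide-by-N) of the R, G and B intensities
#' over the cell's mask pixels only; background pixels in the crop never
#' enter the statistics.
#'
#' @param region A `"cell_region"` with an `rgb_crop`.
#' @param use_filled Use the filled mask (default) or the raw mask.
#' @return Named numeric: `mean_r, mean_g, mean_b, var_r, var_g, var_b`.
#' @export
color_stats <- function(region, use_filled = TRUE) {
  stopifnot(inherits(region, "cell_region"))
  if (is.null(region$rgb_crop)) stop("region carries no RGB crop")
  m <- if (use_filled) region$filled_mask else region$mask
  if (!any(m)) stop("empty mask")
  out <- numeric(6)
  names(out) <- c("mean_r", "mean_g", "mean_b", "var_r", "var_g", "var_b")
  for (ch in 1:3) {
    v <- region$rgb_crop[, , ch][m]
    out[ch] <- mean(v)
    out[ch + 3] <- mean((v - mean(v))^2)
  }
  out
}

#' Quantize masked intensities into K gray levels
#'
#' Min--max linear binning of the masked pixels into levels `1..K` with
#' half-open bins `[lo, hi)` (a pixel exactly on an interior bin edge falls
#' in the lower bin) and a closed top bin.  A constant crop maps to level 1.
#' Pixels outside the mask get level 0 (excluded from all texture counting).
#'
#' @param gray_crop Numeric matrix.
#' @param mask Logical matrix, same shape.
#' @param levels Number of gray levels K (default 8).
#' @return Integer matrix of levels, 0 outside the mask.
#' @export
quantize_levels <- function(gray_crop, mask, levels = 8) {
  stopifnot(levels >= 2, all(dim(gray_crop) == dim(mask)))
  out <- matrix(0L, nrow(gray_crop), ncol(gray_crop))
  v <- gray_crop[mask]
  if (!length(v)) return(out)
  lo <- min(v); hi <- max(v)
  lev <- if (hi <= lo) rep(1L, length(v)) else {
    # interior edges belong to the bin above them being open: floor puts an
    # edge value into the lower... floor((x-lo)/w) counts an interior edge
    # into the upper bin, so nudge edges down with a strict-lower rule
    w <- (hi - lo) / levels
    k <- floor((v - lo) / w) + 1L
    on_edge <- (v - lo) %% w == 0 & v > lo
    k[on_edge] <- k[on_edge] - 1L
    pmin(as.integer(k), levels)
  }
  out[mask] <- lev
  out
}

glcm_offset <- function(angle) {
  switch(as.character(angle),
         "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of level pairs at unit distance along one of the
#' four lattice directions; both pixels of a pair must lie inside the mask.
#' Symmetric mode (default) adds the transpose before normalizing, the
#' convention used for angle-averaged Haralick features.
#'
#' @param level_image Integer matrix from [quantize_levels()] (0 = outside).
#' @param mask Logical matrix.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param distance Offset length in pixels (default 1).
#' @param symmetric Add the transpose (default TRUE).
#' @param levels Number of gray levels (default 8).
#' @return List of class `"glcm"`: `counts`, `p` (normalized), `angle`,
#'   `no_pairs` flag.
#' @export
build_glcm <- function(level_image, mask, angle, distance = 1,
                       symmetric = TRUE, levels = 8) {
  off <- glcm_offset(angle) * as.integer(distance)
  li <- level_image
  li[!mask] <- 0L
  sh <- shift_mat(li, -off[1], -off[2], 0L)  # value of the pixel at +offset
  sel <- li > 0L & sh > 0L
  counts <- matrix(0, levels, levels)
  if (any(sel)) {
    tab <- table(factor(li[sel], levels = 1:levels),
                 factor(sh[sel], levels = 1:levels))
    counts <- matrix(as.numeric(tab), levels, levels)
  }
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  structure(list(counts = counts,
                 p = if (tot > 0) counts / tot else counts,
                 angle = angle, distance = distance, symmetric = symmetric,
                 no_pairs = tot == 0),
            class = "glcm")
}

#' Haralick-type features of a GLCM
#'
#' Maximum probability, correlation, contrast, energy (angular second
#' moment), homogeneity and entropy (base 2, with `0 log 0 := 0`) of a
#' normalized co-occurrence matrix.  Correlation is undefined when either
#' marginal standard deviation vanishes (e.g. a constant cell); it is
#' reported as 0 with attribute `correlation_defined = FALSE`.
#'
#' @param m A `"glcm"` object.
#' @return Named numeric vector of 6 features with attribute
#'   `correlation_defined`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$p
  K <- nrow(p)
  i <- matrix(1:K, K, K); j <- t(i)
  pr <- rowSums(p); pc <- colSums(p)
  mr <- sum((1:K) * pr); mc <- sum((1:K) * pc)
  sr <- sqrt(sum(((1:K) - mr)^2 * pr)); sc <- sqrt(sum(((1:K) - mc)^2 * pc))
  corr_def <- sr > 0 && sc > 0
  corr <- if (corr_def) sum((i - mr) * (j - mc) * p) / (sr * sc) else 0
  plog <- ifelse(p > 0, p * log2(p), 0)
  out <- c(max_probability = max(p),
           correlation = corr,
           contrast = sum((i - j)^2 * p),
           energy = sum(p^2),
           homogeneity = sum(p / (1 + abs(i - j))),
           entropy = -sum(plog))
  attr(out, "correlation_defined") <- corr_def
  out
}

# scan lines (lists of index vectors into the matrix) along a direction
scan_lines <- function(nr, nc, angle) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  switch(as.character(angle),
    "0"   = lapply(seq_len(nr), function(r) idx[r, ]),
    "90"  = lapply(seq_len(nc), function(c) idx[, c]),
    # 45 degrees: scan towards upper-right; lines of constant row+col
    "45"  = {
      s <- row(idx) + col(idx)
      lapply(split(seq_len(nr * nc), s), function(v) v[order(-((v - 1) %% nr))])
    },
    # 135 degrees: towards upper-left; lines of constant col-row
    "135" = {
      s <- col(idx) - row(idx)
      lapply(split(seq_len(nr * nc), s), function(v) v[order(((v - 1) %% nr))])
    },
    stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along the scan lines of one
#' direction; runs are truncated wherever the mask is left, so background
#' pixels never join two runs.
#'
#' @inheritParams build_glcm
#' @return List of class `"glrlm"`: `p` (levels x max-run-length counts),
#'   `R` (total runs), `n_px` (masked pixels in scope), `angle`, `no_runs`.
#' @export
build_glrlm <- function(level_image, mask, angle, levels = 8) {
  li <- level_image
  li[!mask] <- 0L
  lines <- scan_lines(nrow(li), ncol(li), angle)
  # concatenate all scan lines with 0 separators; 0-level runs are discarded
  flat <- unlist(lapply(lines, function(ix) c(li[ix], 0L)), use.names = FALSE)
  r <- rle(flat)
  keep <- r$values > 0L
  lev <- r$values[keep]; len <- r$lengths[keep]
  if (!length(lev)) {
    return(structure(list(p = matrix(0, levels, 1), R = 0L, n_px = 0L,
                          angle = angle, no_runs = TRUE), class = "glrlm"))
  }
  kmax <- max(len)
  p <- matrix(0, levels, kmax)
  tab <- table(factor(lev, levels = 1:levels), factor(len, levels = 1:kmax))
  p[] <- as.numeric(tab)
  structure(list(p = p, R = sum(p), n_px = sum(mask & level_image > 0L),
                 angle = angle, no_runs = FALSE), class = "glrlm")
}

#' Run-length texture features
#'
#' The eleven classical run-length statistics: short/long run emphasis (SRE,
#' LRE), gray-level and run-length nonuniformity (GLN, RLN), run percentage
#' (RP = total runs / pixels), low/high gray-level run emphasis (LGRE,
#' HGRE), and the four joint emphases (SRLGE, SRHGE, LRLGE, LRHGE).  Gray
#' levels are indexed from 1 so the divisions by `i^2` are defined at the
#' darkest level.
#'
#' @param m A `"glrlm"` object.
#' @return Named numeric vector of 11 features (all 0 if the matrix holds no
#'   runs, flagged via attribute `no_runs`).
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  nm <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
          "srlge", "srhge", "lrlge", "lrhge")
  if (isTRUE(m$no_runs) || m$R == 0) {
    out <- stats::setNames(numeric(11), nm)
    attr(out, "no_runs") <- TRUE
    return(out)
  }
  p <- m$p; R <- m$R
  i <- matrix(seq_len(nrow(p)), nrow(p), ncol(p))
  j <- t(matrix(seq_len(ncol(p)), ncol(p), nrow(p)))
  out <- c(
    sre   = sum(p / j^2) / R,
    lre   = sum(p * j^2) / R,
    gln   = sum(rowSums(p)^2) / R,
    rln   = sum(colSums(p)^2) / R,
    rp    = R / m$n_px,
    lgre  = sum(p / i^2) / R,
    hgre  = sum(p * i^2) / R,
    srlge = sum(p / (i^2 * j^2)) / R,
    srhge = sum(p * i^2 / j^2) / R,
    lrlge = sum(p * j^2 / i^2) / R,
    lrhge = sum(p * i^2 * j^2) / R
  )
  names(out) <- nm
  attr(out, "no_runs") <- FALSE
  out
}

#' Angle-averaged GLCM and GLRLM features of a cell
#'
#' Quantizes the cell's enhanced gray crop to `levels` gray levels over the
#' filled mask, computes the 6 GLCM and 11 GLRLM features at 0, 45, 90 and
#' 135 degrees, and returns the per-feature means over the four directions.
#'
#' @param region A `"cell_region"` with a `gray_crop`.
#' @param levels Gray levels (default 8).
#' @param distance GLCM offset distance (default 1).
#' @return Named numeric of 17 values: `glcm_*` (6) then `glrlm_*` (11).
#' @export
angle_averaged_features <- function(region, levels = 8, distance = 1) {
  stopifnot(inherits(region, "cell_region"))
  if (is.null(region$gray_crop)) stop("region carries no gray crop")
  mask <- region$filled_mask
  li <- quantize_levels(region$gray_crop, mask, levels)
  angles <- c(0, 45, 90, 135)
  gl <- rowMeans(vapply(angles, function(a)
    glcm_features(build_glcm(li, mask, a, distance = distance, levels = levels)),
    numeric(6)))
  rl <- rowMeans(vapply(angles, function(a)
    glrlm_features(build_glrlm(li, mask, a, levels = levels)),
    numeric(11)))
  stats::setNames(c(gl, rl),
                  c(paste0("glcm_", names(gl)), paste0("glrlm_", names(rl))))
}
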