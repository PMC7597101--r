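# raster fixtures and brute-force oracles used across test files

disk_mask <- function(r, n = 2 * r + 11) {
  cr <- (n + 1) / 2
  sqrt(outer((1:n - cr)^2, (1:n - cr)^2, "+")) <= r
}

square_mask <- function(side, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

ellipse_mask <- function(theta, a = 30, b = 18, n = 101) {
  cr <- (n + 1) / 2
  xs <- outer(1:n - cr, rep(1, n))
  ys <- outer(rep(1, n), 1:n - cr)
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# minimal cell_region wrapper for raw masks
make_region <- function(mask, filled = mask, rgb = NULL, gray = NULL, id = 1L) {
  structure(list(cell_id = id,
                 bbox = c(row0 = 0L, col0 = 0L,
                          row1 = nrow(mask), col1 = ncol(mask)),
                 mask = mask, filled_mask = filled,
                 hole_mask = filled & !mask,
                 area = sum(mask), hole_area = sum(filled & !mask),
                 clump = FALSE, rgb_crop = rgb, gray_crop = gray),
            class = "cell_region")
}

# brute-force Otsu: exhaustive search of the between-class variance over all
# 256 integer thresholds
brute_otsu <- function(img) {
  v <- as.integer(round(img))
  best <- -Inf; thr <- NA
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; thr <- t }
  }
  thr
}

# brute-force GLCM: explicit double loop over all in-mask pixel pairs
brute_glcm <- function(levels_img, mask, angle, levels = 8, symmetric = TRUE) {
  off <- switch(as.character(angle), "0" = c(0, 1), "45" = c(-1, 1),
                "90" = c(-1, 0), "135" = c(-1, -1))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || c2 < 1 || r2 > nrow(mask) || c2 > ncol(mask)) next
    if (mask[r, c] && mask[r2, c2])
      counts[levels_img[r, c], levels_img[r2, c2]] <-
        counts[levels_img[r, c], levels_img[r2, c2]] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

# brute-force GLRLM: walk every scan line pixel by pixel
brute_glrlm <- function(levels_img, mask, angle, levels = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  step <- switch(as.character(angle), "0" = c(0, 1), "45" = c(-1, 1),
                 "90" = c(-1, 0), "135" = c(-1, -1))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    if (pr < 1 || pc < 1 || pr > nr || pc > nc)
      starts[[length(starts) + 1]] <- c(r, c)
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur_lev <- 0L; cur_len <- 0L
    while (r >= 1 && c >= 1 && r <= nr && c <= nc) {
      lev <- if (mask[r, c]) levels_img[r, c] else 0L
      if (lev == cur_lev && lev > 0L) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_lev > 0L) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- lev; cur_len <- if (lev > 0L) 1L else 0L
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (cur_lev > 0L) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  if (!length(runs)) return(matrix(0, levels, 1))
  rm <- do.call(rbind, runs)
  p <- matrix(0, levels, max(rm[, 2]))
  for (i in seq_len(nrow(rm))) p[rm[i, 1], rm[i, 2]] <- p[rm[i, 1], rm[i, 2]] + 1
  p
}

# tiny RGB synthetic crop: flat colour disk on a light background
flat_cell_crop <- function(mask, color = c(200, 120, 125), bg = c(235, 228, 230)) {
  arr <- array(0, dim = c(dim(mask), 3))
  for (ch in 1:3) arr[, , ch] <- ifelse(mask, color[ch], bg[ch])
  arr
}
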