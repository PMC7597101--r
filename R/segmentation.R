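#' Global (Otsu) threshold
#'
#' Otsu's threshold on the intensity histogram.  For stained smears the cells
#' are darker than the background, so the darker side of the threshold is
#' taken as foreground by default; `polarity = "light"` inverts this for
#' inverted material.
#'
#' @param image Numeric matrix on the 0--255 scale.
#' @param polarity `"dark"` (default; foreground = darker class) or `"light"`.
#' @return Logical matrix (TRUE = foreground) with the threshold attached as
#'   attribute `"threshold"`.
#' @export
global_threshold <- function(image, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  if (length(image) == 0) stop("empty image")
  if (max(image) <= min(image)) {
    warning("constant image: no threshold exists; returning an empty mask")
    out <- matrix(FALSE, nrow(image), ncol(image))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- EBImage::otsu(image / 255, range = c(0, 1), levels = 256) * 255
  mask <- if (polarity == "dark") image <= thr else image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Remove white blood cells by XOR of the two binarizations
#'
#' The first binarization (of the enhanced image) contains all cells; the
#' second (of the quantized image) contains essentially only the WBCs, whose
#' nuclei are the only pixels dark enough to fall to quantization level zero.
#' The pixelwise exclusive OR of the two masks removes the WBCs and leaves
#' the red cells.
#'
#' Because the two masks cut the soft stain edge of a WBC at different
#' intensities, plain XOR leaves a thin ring around each removed WBC; the
#' alternative mode dilates the WBC mask by `wbc_dilate` pixels and removes
#' it with AND-NOT, which eliminates the ring.  The pipeline defaults to
#' `wbc_dilate = 2`, `mode = "andnot"`; this function's own defaults are the
#' plain XOR.
#'
#' @param original_mask Logical matrix, binarized enhanced image (all cells).
#' @param quantized_mask Logical matrix, binarized quantized image (WBCs).
#' @param wbc_dilate Dilation radius (px) applied to `quantized_mask` before
#'   removal; 0 disables.
#' @param mode `"xor"` (default) or `"andnot"`.
#' @return Logical RBC mask.
#' @export
remove_wbc_xor <- function(original_mask, quantized_mask, wbc_dilate = 0,
                           mode = c("xor", "andnot")) {
  mode <- match.arg(mode)
  if (!all(dim(original_mask) == dim(quantized_mask)))
    stop("mask dimensions differ: ", paste(dim(original_mask), collapse = "x"),
         " vs ", paste(dim(quantized_mask), collapse = "x"))
  om <- original_mask == TRUE
  qm <- quantized_mask == TRUE
  if (wbc_dilate > 0 && any(qm)) {
    brush <- EBImage::makeBrush(2L * as.integer(wbc_dilate) + 1L, shape = "disc")
    qm <- EBImage::dilate(qm * 1, brush) > 0
  }
  if (mode == "xor") om != qm else om & !qm
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (off in list(c(1, 1), c(1, -1))) {
    sh <- shift_mat(lab, off[1], off[2], 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], sh[sel]))
      for (r in seq_len(nrow(pairs))) union2(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Split a binary mask into per-cell regions
#'
#' 8-connected component labeling, minimum-area filtering, optional removal
#' of frame-touching components, hole closure, and deterministic ordering by
#' bounding-box origin.  Components whose area exceeds 1.8x the median region
#' area are flagged as probable clumps of touching cells (they are passed
#' through, not split).
#'
#' @param mask Logical matrix.
#' @param min_area_px Components smaller than this are dropped.
#' @param border_policy `"keep"` or `"drop"` components touching the frame.
#' @param rgb Optional `h x w x 3` source image; per-region crops attached.
#' @param gray Optional gray image (e.g. the enhanced channel); crops attached.
#' @return List of `"cell_region"` objects with fields `cell_id`, `bbox`
#'   (row0, col0, row1, col1; half-open, 0-based), `mask`, `filled_mask`,
#'   `hole_mask`, `area`, `hole_area`, `clump`, and optional `rgb_crop`,
#'   `gray_crop`.
#' @export
extract_cells <- function(mask, min_area_px = 1, border_policy = c("drop", "keep"),
                          rgb = NULL, gray = NULL) {
  border_policy <- match.arg(border_policy)
  stopifnot(min_area_px >= 1)
  if (!any(mask)) return(list())
  lab <- label_components8(mask)
  ids <- seq_len(max(lab))
  regions <- list()
  for (k in ids) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_area_px) next
    r0 <- min(px[, 1]); r1 <- max(px[, 1]); c0 <- min(px[, 2]); c1 <- max(px[, 2])
    if (border_policy == "drop" &&
        (r0 == 1 || c0 == 1 || r1 == nrow(mask) || c1 == ncol(mask))) next
    m <- lab[r0:r1, c0:c1, drop = FALSE] == k
    fm <- matrix(EBImage::fillHull(m * 1) > 0, nrow(m), ncol(m))
    reg <- structure(list(
      cell_id = NA_integer_,
      bbox = c(row0 = r0 - 1L, col0 = c0 - 1L, row1 = r1, col1 = c1),
      mask = m,
      filled_mask = fm,
      hole_mask = fm & !m,
      area = sum(m),
      hole_area = sum(fm & !m),
      clump = FALSE
    ), class = "cell_region")
    if (!is.null(rgb)) reg$rgb_crop <- rgb[r0:r1, c0:c1, , drop = FALSE]
    if (!is.null(gray)) reg$gray_crop <- gray[r0:r1, c0:c1, drop = FALSE]
    regions[[length(regions) + 1L]] <- reg
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) r$bbox[["row0"]], 0),
               vapply(regions, function(r) r$bbox[["col0"]], 0))
  regions <- regions[ord]
  areas <- vapply(regions, `[[`, 0, "area")
  med <- stats::median(areas)
  for (i in seq_along(regions)) {
    regions[[i]]$cell_id <- i
    regions[[i]]$clump <- areas[i] > 1.8 * med
  }
  regions
}

#' @export
print.cell_region <- function(x, ...) {
  cat("Cell region #", x$cell_id, ": area ", x$area, " px, hole ", x$hole_area,
      " px, bbox [", paste(x$bbox, collapse = ", "), ")",
      if (isTRUE(x$clump)) " [clump]", "\n", sep = "")
  invisible(x)
}

#' Default minimum region area
#'
#' Area of a disk whose radius is half the smallest configured microcyte
#' radius; anything smaller (platelets, debris) is not a credible red cell.
#'
#' @param class_params See [default_class_parameters()].
#' @return Integer pixel area.
#' @export
default_min_area <- function(class_params = default_class_parameters()) {
  rmin <- min(class_params$microcytic_hypochromic$radius_range_px)
  as.integer(round(pi * (rmin / 2)^2))
}

#' Segment the red blood cells of an RGB smear
#'
#' Full segmentation stage: preprocessing, two-step binarization (enhanced
#' image -> all cells; quantized image -> WBCs), WBC removal, and per-cell
#' region extraction with RGB/gray crops attached.
#'
#' @param rgb_image `h x w x 3` array, 0--255.
#' @param min_area_px Minimum region area; default [default_min_area()].
#' @param border_policy Passed to [extract_cells()].
#' @param wbc_dilate,wbc_mode WBC removal parameters; the defaults (radius 2,
#'   AND-NOT) remove the threshold-mismatch ring that plain XOR leaves around
#'   each WBC.
#' @param wbc_min_area Components of the WBC-candidate mask smaller than this
#'   are discarded before removal.  WBCs (>= 12 um diameter) are larger than
#'   any red cell, so the default -- the pixel area of a 12 um disk at
#'   0.2 um/px -- keeps the removal stage from eating dark red cells in
#'   fields that contain no WBC at all (where the darkest structure in the
#'   quantized image is inevitably a red cell).
#' @param bcet_mean,median_window Passed to [preprocess_smear()].
#' @return List with `gray`, `quantized`, `mask_all`, `mask_wbc`, `rbc_mask`,
#'   and `regions` (list of [extract_cells()] regions).
#' @export
segment_smear <- function(rgb_image, min_area_px = default_min_area(),
                          border_policy = "drop",
                          wbc_dilate = 2, wbc_mode = "andnot",
                          wbc_min_area = round(pi * 30^2),
                          bcet_mean = NULL, median_window = 3) {
  pre <- preprocess_smear(rgb_image, bcet_mean = bcet_mean,
                          median_window = median_window)
  # two-step binarization: the *original* (smoothed, un-enhanced) channel is
  # binarized for the all-cells mask; the quantized enhanced image for WBCs
  raw <- median_smooth(select_green_channel(rgb_image), median_window)
  mask_all <- global_threshold(raw)
  mask_wbc <- if (max(pre$quantized$pixels) > min(pre$quantized$pixels)) {
    global_threshold(pre$quantized$pixels)
  } else {
    matrix(FALSE, nrow(pre$gray), ncol(pre$gray))
  }
  if (any(mask_wbc) && wbc_min_area > 0) {
    lab <- label_components8(mask_wbc)
    sizes <- tabulate(lab[lab > 0L])
    mask_wbc <- mask_wbc & matrix(sizes[ifelse(lab > 0L, lab, 1L)] >= wbc_min_area &
                                    lab > 0L, nrow(lab), ncol(lab))
  }
  rbc_mask <- remove_wbc_xor(mask_all, mask_wbc, wbc_dilate = wbc_dilate,
                             mode = wbc_mode)
  regions <- extract_cells(rbc_mask, min_area_px = min_area_px,
                           border_policy = border_policy,
                           rgb = rgb_image, gray = pre$gray)
  list(gray = pre$gray, quantized = pre$quantized, mask_all = mask_all,
       mask_wbc = mask_wbc, rbc_mask = rbc_mask, regions = regions)
}
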