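#' Cell classes modelled by the simulator
#'
#' Seven red-cell morphology classes (size x chromicity combinations that
#' occur in anemia workups), plus white blood cells and platelets.
#'
#' @return Character vector of class names.
#' @export
rbc_classes <- function() {
  c("microcytic_hypochromic", "microcytic_normochromic", "microcytic_hyperchromic",
    "normocytic_hypochromic", "normocytic_normochromic",
    "macrocytic_hypochromic", "macrocytic_hyperchromic",
    "wbc", "platelet")
}

#' Default per-class rendering parameters
#'
#' Maps every cell class to a radius range (pixels), a central-pallor ratio
#' range and a base stain colour.  Sizes are anchored in micrometres and
#' converted at `um_per_px`: normal RBC diameters span 6.2--8.2 um, so
#' microcytes are drawn strictly below and macrocytes strictly above that
#' band (no overlap at the defaults).  The central pallor -- the lighter disk
#' at the cell centre where the biconcave cell is thinnest -- encodes
#' chromicity: hypochromic (hemoglobin-poor) cells get a large pallor,
#' normochromic a moderate one, and hyperchromic (hemoglobin-dense) cells
#' none at all.  The pallor-to-cell ratios are simulator assumptions (no
#' quantitative reference values exist); stain colours approximate a
#' Romanowsky-stained smear: salmon-red RBCs whose stain deepens with
#' hemoglobin content, dark purple WBC nuclei, small violet platelets.
#'
#' @param um_per_px Pixel pitch in micrometres per pixel (default 0.2).
#' @return Named list; each element has `radius_range_px`,
#'   `pallor_ratio_range` and `color` (RGB in 0--255).
#' @export
default_class_parameters <- function(um_per_px = 0.2) {
  r_px <- function(d_lo, d_hi) c(d_lo, d_hi) / 2 / um_per_px
  pall <- list(hypo = c(0.55, 0.70), normo = c(0.30, 0.45), hyper = c(0, 0))
  col <- list(hypo = c(215, 150, 158), normo = c(205, 140, 145),
              hyper = c(195, 130, 135))
  micro <- r_px(4.2, 5.8); normo <- r_px(6.2, 8.2); macro <- r_px(8.6, 10.6)
  entry <- function(rr, chrom) list(radius_range_px = rr,
                                    pallor_ratio_range = pall[[chrom]],
                                    color = col[[chrom]])
  list(
    microcytic_hypochromic  = entry(micro, "hypo"),
    microcytic_normochromic = entry(micro, "normo"),
    microcytic_hyperchromic = entry(micro, "hyper"),
    normocytic_hypochromic  = entry(normo, "hypo"),
    normocytic_normochromic = entry(normo, "normo"),
    macrocytic_hypochromic  = entry(macro, "hypo"),
    macrocytic_hyperchromic = entry(macro, "hyper"),
    wbc      = list(radius_range_px = r_px(12, 16),
                    pallor_ratio_range = c(0, 0), color = c(95, 35, 120)),
    platelet = list(radius_range_px = r_px(2.0, 3.0),
                    pallor_ratio_range = c(0, 0), color = c(160, 110, 170))
  )
}

#' Simulation configuration
#'
#' Bundles everything [simulate_smear()] needs.  Defaults emulate a thin,
#' well-spread smear field: cells drawn as anti-aliased stained disks with a
#' concentric lighter pallor disk, a pale pink background, a mild
#' multiplicative linear illumination gradient, and additive Gaussian pixel
#' noise.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param counts_per_class Named integer vector, names from [rbc_classes()].
#' @param class_params Per-class parameters, see [default_class_parameters()].
#' @param overlap_fraction Allowed bounding-disk intersection as a fraction of
#'   the summed radii; 0 means disjoint cells.
#' @param min_separation_px Extra gap (px) enforced between cell boundaries
#'   when `overlap_fraction = 0`, so tangent cells cannot fuse into one
#'   connected component after thresholding.
#' @param illumination_gradient Peak-to-peak relative amplitude of the linear
#'   illumination field (0 disables it).
#' @param noise_sd Standard deviation of additive Gaussian noise (gray levels).
#' @param background Background RGB triple.
#' @param pallor_lightening Blend factor of the pallor disk towards the
#'   background colour (1 = pallor identical to background).
#' @param um_per_px Pixel pitch used by `class_params` defaults.
#' @param seed Integer seed; the same config is guaranteed to reproduce the
#'   same image and ground truth byte for byte.
#' @return A list of class `"smear_config"`.
#' @export
smear_config <- function(image_size = c(256, 256),
                         counts_per_class = c(normocytic_normochromic = 10),
                         class_params = default_class_parameters(um_per_px),
                         overlap_fraction = 0,
                         min_separation_px = 4,
                         illumination_gradient = 0.08,
                         noise_sd = 3,
                         background = c(235, 228, 230),
                         pallor_lightening = 0.8,
                         um_per_px = 0.2,
                         seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 8),
            all(counts_per_class >= 0), overlap_fraction >= 0,
            overlap_fraction < 1, noise_sd >= 0)
  unknown <- setdiff(names(counts_per_class), rbc_classes())
  if (length(unknown)) stop("unknown cell class(es): ", paste(unknown, collapse = ", "))
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  structure(list(image_size = as.integer(image_size),
                 counts_per_class = counts_per_class,
                 class_params = class_params,
                 overlap_fraction = overlap_fraction,
                 min_separation_px = min_separation_px,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd,
                 background = background,
                 pallor_lightening = pallor_lightening,
                 um_per_px = um_per_px,
                 seed = as.integer(seed)),
            class = "smear_config")
}

#' Simulate a stained blood-smear image with pixel-level ground truth
#'
#' Places the requested cells by rejection sampling (whole cell inside the
#' frame, pairwise distance respecting `overlap_fraction`), renders each as
#' an anti-aliased stained disk with an optional concentric pallor disk,
#' then applies the illumination gradient and pixel noise.  WBCs are larger
#' and darker-stained than RBCs; platelets are small violet specks.
#'
#' @param config A [smear_config()].
#' @return List of class `"synthetic_smear"` with elements
#'   `image` (`h x w x 3`, 0--255), and `truth`: `label_mask` (integer
#'   matrix, 0 background, k = cell index), `class_per_cell` (character,
#'   indexed by cell), and `cell_specs` (data.frame: cell_id, class, row,
#'   col, radius_px, pallor_ratio; row/col are 0-based pixel coordinates).
#' @export
simulate_smear <- function(config = smear_config()) {
  stopifnot(inherits(config, "smear_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  h <- config$image_size[1]; w <- config$image_size[2]
  counts <- config$counts_per_class[config$counts_per_class > 0]

  specs <- list()
  # placement: rejection sampling against already-placed cells; largest
  # classes first so big cells (WBCs) are not squeezed out of a crowded field
  mean_radius <- vapply(names(counts), function(cl)
    mean(config$class_params[[cl]]$radius_range_px), 0)
  for (cls in names(counts)[order(-mean_radius)]) {
    pars <- config$class_params[[cls]]
    for (i in seq_len(counts[[cls]])) {
      radius <- stats::runif(1, pars$radius_range_px[1], pars$radius_range_px[2])
      pr <- pars$pallor_ratio_range
      pallor <- if (pr[2] > pr[1]) stats::runif(1, pr[1], pr[2]) else pr[1]
      placed <- FALSE
      for (try in seq_len(400L)) {
        r0 <- stats::runif(1, radius + 2, h - radius - 1)
        c0 <- stats::runif(1, radius + 2, w - radius - 1)
        ok <- TRUE
        for (s in specs) {
          lim <- (radius + s$radius) * (1 - config$overlap_fraction)
          if (config$overlap_fraction == 0) lim <- lim + config$min_separation_px
          if (sqrt((r0 - s$row)^2 + (c0 - s$col)^2) < lim) { ok <- FALSE; break }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place a '", cls, "' cell without violating the ",
             "overlap constraint; enlarge the image or reduce counts")
      specs[[length(specs) + 1L]] <- list(cell_class = cls, row = r0, col = c0,
                                          radius = radius, pallor_ratio = pallor)
    }
  }

  img <- array(rep(config$background, each = h * w), dim = c(h, w, 3))
  label <- matrix(0L, h, w)

  for (k in seq_along(specs)) {
    s <- specs[[k]]
    dc <- disk_coverage(h, w, s$row + 1, s$col + 1, s$radius)
    cell_col <- config$class_params[[s$cell_class]]$color
    # pallor disk: cell colour blended towards the background
    pall_col <- cell_col + config$pallor_lightening * (config$background - cell_col)
    pcov <- if (s$pallor_ratio > 0) {
      dp <- disk_coverage(h, w, s$row + 1, s$col + 1, s$radius * s$pallor_ratio)
      # embed the (smaller) pallor window in the cell window
      pm <- matrix(0, length(dc$rows), length(dc$cols),
                   dimnames = list(dc$rows, dc$cols))
      pm[as.character(dp$rows), as.character(dp$cols)] <- dp$cov
      pm
    } else matrix(0, length(dc$rows), length(dc$cols))
    for (ch in 1:3) {
      paint <- cell_col[ch] * (1 - pcov) + pall_col[ch] * pcov
      img[dc$rows, dc$cols, ch] <-
        img[dc$rows, dc$cols, ch] * (1 - dc$cov) + paint * dc$cov
    }
    lab_win <- label[dc$rows, dc$cols]
    lab_win[dc$cov > 0.5] <- k
    label[dc$rows, dc$cols] <- lab_win
  }

  if (config$illumination_gradient > 0) {
    phi <- stats::runif(1, 0, 2 * pi)
    u <- outer((seq_len(h) - 1) / max(h - 1, 1) - 0.5,
               rep(0, w), "+") * cos(phi) +
         outer(rep(0, h), (seq_len(w) - 1) / max(w - 1, 1) - 0.5, "+") * sin(phi)
    grad <- 1 + config$illumination_gradient * u
    for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
  }
  if (config$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 255)

  cell_specs <- if (length(specs)) data.frame(
    cell_id = seq_along(specs),
    class = vapply(specs, `[[`, "", "cell_class"),
    row = vapply(specs, `[[`, 0, "row"),
    col = vapply(specs, `[[`, 0, "col"),
    radius_px = vapply(specs, `[[`, 0, "radius"),
    pallor_ratio = vapply(specs, `[[`, 0, "pallor_ratio"),
    stringsAsFactors = FALSE
  ) else data.frame(cell_id = integer(), class = character(), row = numeric(),
                    col = numeric(), radius_px = numeric(), pallor_ratio = numeric())

  structure(list(
    image = img,
    truth = list(label_mask = label,
                 class_per_cell = cell_specs$class,
                 cell_specs = cell_specs),
    config = config
  ), class = "synthetic_smear")
}

#' @export
print.synthetic_smear <- function(x, ...) {
  cat("Synthetic blood smear:", paste(dim(x$image)[1:2], collapse = " x "),
      "px,", nrow(x$truth$cell_specs), "cells\n")
  if (nrow(x$truth$cell_specs))
    print(table(x$truth$cell_specs$class))
  invisible(x)
}

#' Write a simulated smear to disk
#'
#' Writes `image.png` (8-bit RGB), `label_mask.png` (grayscale, one level per
#' cell id) and `cells.csv` (cell_id, class, row, col, radius_px,
#' pallor_ratio; 0-based coordinates).
#'
#' @param sim A [simulate_smear()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_smear <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_smear"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_png(sim$image, file.path(dir, "image.png"))
  write_label_mask(sim$truth$label_mask, file.path(dir, "label_mask.png"))
  utils::write.csv(sim$truth$cell_specs, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}
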