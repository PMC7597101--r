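## End-to-end orchestration: simulate -> preprocess -> segment -> features ->
## balance -> reduce -> classify -> report, with a frozen 52-column feature
## vector.

#' Names of the 52 per-cell features, in frozen block order
#'
#' Block 1: geometry (5); block 2: RGB statistics (6); block 3: GLCM means
#' (6); block 4: GLRLM means (11); block 5: Gabor MSE then MA (24).
#'
#' @param bank The Gabor bank whose filter ids name block 5.
#' @return Character vector of length 52.
#' @export
feature_names <- function(bank = gabor_bank()) {
  ids <- vapply(bank, `[[`, "", "id")
  c("area", "circularity", "rectangularity", "concavity", "convexity",
    "mean_r", "mean_g", "mean_b", "var_r", "var_g", "var_b",
    paste0("glcm_", c("max_probability", "correlation", "contrast",
                      "energy", "homogeneity", "entropy")),
    paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                       "srlge", "srhge", "lrlge", "lrhge")),
    paste0("gabor_mse_", ids), paste0("gabor_ma_", ids))
}

#' Extract the 52-feature vector of one cell region
#'
#' @param region A `"cell_region"` carrying `rgb_crop` and `gray_crop`.
#' @param bank Gabor bank (default 12 filters).
#' @param levels Gray levels for GLCM/GLRLM (default 8).
#' @return Named numeric of length 52 with attribute `degenerate`.
#' @export
extract_features <- function(region, bank = gabor_bank(), levels = 8) {
  geo <- compute_geometry(region)
  if (isTRUE(geo$degenerate)) {
    out <- stats::setNames(rep(NA_real_, 52), feature_names(bank))
    out["area"] <- geo$area
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  vals <- c(area = geo$area, circularity = geo$circularity,
            rectangularity = geo$rectangularity, concavity = geo$concavity,
            convexity = geo$convexity,
            color_stats(region),
            angle_averaged_features(region, levels = levels),
            extract_gabor(region$gray_crop, region$filled_mask, bank))
  names(vals) <- feature_names(bank)
  attr(vals, "degenerate") <- FALSE
  vals
}

#' Extract features for every region of an image
#'
#' @param regions List of regions from [extract_cells()] or [segment_smear()].
#' @param bank,levels See [extract_features()].
#' @return data.frame: `cell_id`, `degenerate`, then the 52 feature columns.
#' @export
extract_all_features <- function(regions, bank = gabor_bank(), levels = 8) {
  if (!length(regions)) {
    out <- as.data.frame(matrix(numeric(), 0, 54))
    names(out) <- c("cell_id", "degenerate", feature_names(bank))
    return(out)
  }
  rows <- lapply(regions, function(r) {
    v <- extract_features(r, bank = bank, levels = levels)
    data.frame(cell_id = r$cell_id, degenerate = attr(v, "degenerate"),
               t(v), check.names = FALSE)
  })
  do.call(rbind, rows)
}

# majority-overlap matching of segmented regions to ground-truth labels
match_regions_to_truth <- function(regions, truth, min_overlap = 0.5) {
  vapply(regions, function(r) {
    rows <- (r$bbox[["row0"]] + 1):r$bbox[["row1"]]
    cols <- (r$bbox[["col0"]] + 1):r$bbox[["col1"]]
    labs <- truth$label_mask[rows, cols][r$filled_mask]
    labs <- labs[labs > 0]
    if (!length(labs) || length(labs) < min_overlap * r$area) return(NA_character_)
    hit <- as.integer(names(which.max(table(labs))))
    truth$class_per_cell[hit]
  }, character(1))
}

#' Pipeline configuration
#'
#' @param n_images Number of smear fields to simulate.
#' @param image_size Per-field size in pixels.
#' @param counts_per_class Cells per field per class.  The default draws the
#'   five morphology classes commonly contrasted in anemia workups, plus one
#'   WBC per field (the WBC-removal stage needs WBCs to remove).
#' @param folds Cross-validation folds.
#' @param seed Master seed; per-image seeds are derived from it.
#' @param rf_trees,mlp_hidden,epochs Classifier settings.
#' @param lsda_r Reduced dimension (default: classes - 1; `NA` skips LSDA).
#' @param ... Extra arguments stored for [smear_config()].
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_images = 60,
                            image_size = c(256, 256),
                            counts_per_class = c(microcytic_hypochromic = 2,
                                                 normocytic_hypochromic = 2,
                                                 macrocytic_hypochromic = 2,
                                                 microcytic_hyperchromic = 2,
                                                 normocytic_normochromic = 2,
                                                 wbc = 1),
                            folds = 5, seed = 42,
                            rf_trees = 200, mlp_hidden = 64, epochs = 200,
                            lsda_r = NULL, ...) {
  structure(list(n_images = n_images, image_size = image_size,
                 counts_per_class = counts_per_class, folds = folds,
                 seed = as.integer(seed), rf_trees = rf_trees,
                 mlp_hidden = mlp_hidden, epochs = epochs, lsda_r = lsda_r,
                 smear_args = list(...)),
            class = "pipeline_config")
}

#' Run the whole pipeline on simulated smears
#'
#' Simulates `n_images` smear fields, segments each, labels every recovered
#' region by majority overlap with the pixel ground truth, extracts the
#' 52-feature vector per cell, and evaluates the ADASYN + LSDA + ensemble
#' classifier by stratified cross-validation.  Regions matching no modelled
#' RBC class (WBC remnants, platelets, unmatched blobs) and degenerate
#' regions are logged and excluded from training.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (feature CSV, report JSON).
#' @return Object of class `"smear_report"`: the classification report plus
#'   `features` (data.frame incl. `image`, `true_class`), `timings`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bank <- gabor_bank()
  t0 <- proc.time()[["elapsed"]]
  feats <- list()
  rbc <- setdiff(rbc_classes(), c("wbc", "platelet"))
  for (i in seq_len(config$n_images)) {
    args <- c(list(image_size = config$image_size,
                   counts_per_class = config$counts_per_class,
                   seed = config$seed + i), config$smear_args)
    sim <- simulate_smear(do.call(smear_config, args))
    seg <- segment_smear(sim$image)
    if (!length(seg$regions)) next
    fdf <- extract_all_features(seg$regions, bank = bank)
    fdf$true_class <- match_regions_to_truth(seg$regions, sim$truth)
    fdf$image <- i
    feats[[i]] <- fdf
  }
  features <- do.call(rbind, feats)
  t_feat <- proc.time()[["elapsed"]]
  usable <- !features$degenerate & !is.na(features$true_class) &
    features$true_class %in% rbc
  xm <- as.matrix(features[usable, feature_names(bank)])
  ym <- features$true_class[usable]
  rep <- cross_validate(xm, ym, folds = config$folds, seed = config$seed,
                        lsda_r = config$lsda_r, rf_trees = config$rf_trees,
                        mlp_hidden = config$mlp_hidden, epochs = config$epochs)
  t_cv <- proc.time()[["elapsed"]]
  rep$features <- features
  rep$usable <- usable
  rep$config <- config
  rep$timings <- c(feature_extraction = t_feat - t0, cross_validation = t_cv - t_feat)
  class(rep) <- c("smear_report", class(rep))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      macro = rep$macro, accuracy = rep$accuracy,
      per_class = lapply(rep$per_class, function(p)
        p[c("precision", "recall", "f1", "support")]),
      seed = config$seed, folds = config$folds
    ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.smear_report <- function(x, ...) {
  cat("Blood-smear pipeline report:", x$config$n_images, "images,",
      sum(x$usable), "cells used /", nrow(x$features), "segmented\n")
  cat(sprintf("timings: features %.1fs, cross-validation %.1fs\n",
              x$timings[1], x$timings[2]))
  NextMethod()
}
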