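test_that("same seed and config reproduce the smear byte for byte", {
  cfg <- smear_config(counts_per_class = c(normocytic_normochromic = 5,
                                           wbc = 1), seed = 7)
  a <- simulate_smear(cfg)
  b <- simulate_smear(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$label_mask, b$truth$label_mask)
  expect_identical(a$truth$cell_specs, b$truth$cell_specs)
})

test_that("requested cell counts are conserved in the ground truth", {
  cfg <- smear_config(counts_per_class = c(normocytic_normochromic = 5),
                      overlap_fraction = 0, seed = 7)
  sim <- simulate_smear(cfg)
  expect_equal(nrow(sim$truth$cell_specs), 5)
  expect_equal(sort(unique(as.vector(sim$truth$label_mask))), 0:5)
  expect_true(all(sim$truth$class_per_cell == "normocytic_normochromic"))
  # label mask components equal cell count at zero overlap
  lab <- hemosmear:::label_components8(sim$truth$label_mask > 0)
  expect_equal(max(lab), 5)
})

test_that("zero counts give a blank background and empty ground truth", {
  cfg <- smear_config(counts_per_class = c(normocytic_normochromic = 0),
                      noise_sd = 0, illumination_gradient = 0, seed = 1)
  sim <- simulate_smear(cfg)
  expect_equal(nrow(sim$truth$cell_specs), 0)
  expect_true(all(sim$truth$label_mask == 0))
  expect_equal(as.vector(sim$image[1, 1, ]), cfg$background)
  expect_true(max(abs(sweep(sim$image, 3, cfg$background))) < 1e-9)
})

test_that("class-conditional size and pallor statistics match the configuration", {
  cfg <- smear_config(image_size = c(512, 512),
                      counts_per_class = c(microcytic_hypochromic = 20,
                                           macrocytic_hyperchromic = 20),
                      seed = 3)
  sim <- simulate_smear(cfg)
  cs <- sim$truth$cell_specs
  micro <- cs[cs$class == "microcytic_hypochromic", ]
  macro <- cs[cs$class == "macrocytic_hyperchromic", ]
  expect_lt(mean(micro$radius_px), mean(macro$radius_px))
  expect_gt(mean(micro$pallor_ratio), mean(macro$pallor_ratio))
  # recovered values stay inside the configured ranges
  pars <- cfg$class_params
  expect_true(all(micro$radius_px >= pars$microcytic_hypochromic$radius_range_px[1] &
                  micro$radius_px <= pars$microcytic_hypochromic$radius_range_px[2]))
  expect_true(all(micro$pallor_ratio >= pars$microcytic_hypochromic$pallor_ratio_range[1] &
                  micro$pallor_ratio <= pars$microcytic_hypochromic$pallor_ratio_range[2]))
  expect_true(all(macro$pallor_ratio == 0))
})

test_that("impossible placements fail with the offending class named", {
  cfg <- smear_config(image_size = c(96, 96),
                      counts_per_class = c(wbc = 20), seed = 1)
  expect_error(simulate_smear(cfg), "wbc")
})

test_that("default class parameters respect the size and pallor orderings", {
  p <- default_class_parameters()
  expect_lt(max(p$microcytic_hypochromic$radius_range_px),
            min(p$normocytic_normochromic$radius_range_px))
  expect_lt(max(p$normocytic_normochromic$radius_range_px),
            min(p$macrocytic_hypochromic$radius_range_px))
  expect_gt(min(p$microcytic_hypochromic$pallor_ratio_range),
            max(p$microcytic_normochromic$pallor_ratio_range))
  expect_equal(p$microcytic_hyperchromic$pallor_ratio_range, c(0, 0))
  expect_equal(p$macrocytic_hyperchromic$pallor_ratio_range, c(0, 0))
  # at 0.2 um/px the normocyte radius range maps back to 6.2-8.2 um diameter
  expect_equal(p$normocytic_normochromic$radius_range_px * 2 * 0.2, c(6.2, 8.2))
  # WBCs larger than every RBC class
  expect_gt(min(p$wbc$radius_range_px), max(p$macrocytic_hyperchromic$radius_range_px))
})

test_that("cells render with the configured staining contrast", {
  cfg <- smear_config(counts_per_class = c(normocytic_normochromic = 3, wbc = 1),
                      noise_sd = 0, illumination_gradient = 0, seed = 5)
  sim <- simulate_smear(cfg)
  cs <- sim$truth$cell_specs
  g <- sim$image[, , 2]
  for (i in seq_len(nrow(cs))) {
    body <- g[round(cs$row[i]) + 1 + round(0.7 * cs$radius_px[i]), round(cs$col[i]) + 1]
    expected <- cfg$class_params[[cs$class[i]]]$color[2]
    expect_equal(body, expected, tolerance = 1e-6)
  }
  # WBC darker than RBC in green
  wbc <- cs$class == "wbc"
  expect_lt(cfg$class_params$wbc$color[2],
            cfg$class_params$normocytic_normochromic$color[2])
})

test_that("written smear artifacts round-trip", {
  dir <- withr::local_tempdir()
  cfg <- smear_config(counts_per_class = c(normocytic_normochromic = 3), seed = 2)
  sim <- simulate_smear(cfg)
  write_smear(sim, dir)
  img <- read_image_rgb(file.path(dir, "image.png"))
  expect_equal(dim(img), dim(sim$image))
  expect_lt(max(abs(img - sim$image)), 0.51)  # 8-bit quantization only
  cells <- read.csv(file.path(dir, "cells.csv"))
  expect_equal(nrow(cells), 3)
})
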