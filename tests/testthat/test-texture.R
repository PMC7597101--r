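test_that("colour statistics are population moments over mask pixels only", {
  m <- matrix(TRUE, 2, 2)
  rgb <- flat_cell_crop(m, color = c(200, 10, 10))
  cs <- color_stats(make_region(m, rgb = rgb))
  expect_equal(unname(cs["mean_r"]), 200)
  expect_equal(unname(cs["var_r"]), 0)
  # two-pixel cell with R in {100, 200}: population variance 2500
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  rgb2 <- flat_cell_crop(m2)
  rgb2[, , 1][m2] <- c(100, 200)
  cs2 <- color_stats(make_region(m2, rgb = rgb2))
  expect_equal(unname(cs2["mean_r"]), 150)
  expect_equal(unname(cs2["var_r"]), 2500)
  # recolouring the background does not move the statistics
  rgb3 <- rgb2; rgb3[, , 1][!m2] <- 0
  expect_equal(color_stats(make_region(m2, rgb = rgb3)), cs2)
  expect_error(color_stats(make_region(matrix(FALSE, 2, 2), rgb = rgb2)), "empty")
})

test_that("level quantization uses half-open bins with a closed top bin", {
  m <- matrix(TRUE, 1, 4)
  q <- quantize_levels(matrix(c(0, 255, 127.5, 31.875), 1, 4), m, 8)
  expect_equal(as.vector(q), c(1, 8, 4, 1))
  # constant crop maps to level 1
  qc <- quantize_levels(matrix(7, 2, 2), matrix(TRUE, 2, 2), 8)
  expect_true(all(qc == 1))
  # outside-mask pixels are level 0
  mm <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(as.vector(quantize_levels(matrix(c(5, 9), 1, 2), mm, 8)), c(1, 0))
})

test_that("GLCM matches hand-enumerated pairs on tiny images", {
  li <- matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  m <- matrix(TRUE, 2, 2)
  g0 <- build_glcm(li, m, 0)
  expect_equal(g0$p[1, 1], 0.5); expect_equal(g0$p[2, 2], 0.5)
  g90 <- build_glcm(li, m, 90)
  expect_equal(g90$p[1, 2], 0.5); expect_equal(g90$p[2, 1], 0.5)
  gc <- build_glcm(matrix(1L, 3, 3), matrix(TRUE, 3, 3), 0)
  expect_equal(gc$p[1, 1], 1)
})

test_that("GLCM features take their closed-form values on canonical matrices", {
  li <- matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  f <- glcm_features(build_glcm(li, matrix(TRUE, 2, 2), 0))
  expect_equal(unname(f["max_probability"]), 0.5)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["entropy"]), 1)
  expect_equal(unname(f["correlation"]), 1)
  # constant image: energy 1, entropy 0, contrast 0, correlation undefined
  fc <- glcm_features(build_glcm(matrix(1L, 3, 3), matrix(TRUE, 3, 3), 0))
  expect_equal(unname(fc["energy"]), 1)
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["contrast"]), 0)
  expect_false(attr(fc, "correlation_defined"))
  expect_equal(unname(fc["correlation"]), 0)
  # uniform matrix: entropy = 2 log2 K = 6 bits at K = 8
  gu <- structure(list(p = matrix(1 / 64, 8, 8)), class = "glcm")
  expect_equal(unname(glcm_features(gu)["entropy"]), 6)
})

test_that("GLRLM matches hand-enumerated runs", {
  row1 <- matrix(c(1L, 1L, 1L, 2L, 2L, 3L), 1, 6)
  rl <- build_glrlm(row1, matrix(TRUE, 1, 6), 0)
  expect_equal(rl$R, 3)
  expect_equal(rl$p[1, 3], 1); expect_equal(rl$p[2, 2], 1); expect_equal(rl$p[3, 1], 1)
  # constant 5x1 column scanned vertically: one run of length 5
  col5 <- matrix(2L, 5, 1)
  rl2 <- build_glrlm(col5, matrix(TRUE, 5, 1), 90)
  expect_equal(rl2$R, 1); expect_equal(rl2$p[2, 5], 1)
  # checkerboard: 16 unit runs horizontally
  cb <- matrix(rep(c(1L, 2L), 8), 4, 4); cb[, c(2, 4)] <- 3L - cb[, c(2, 4)]
  expect_equal(build_glrlm(cb, matrix(TRUE, 4, 4), 0)$R, 16)
})

test_that("GLRLM features reproduce hand-derived values", {
  rl <- build_glrlm(matrix(c(1L, 1L, 1L, 2L, 2L, 3L), 1, 6), matrix(TRUE, 1, 6), 0)
  f <- glrlm_features(rl)
  expect_equal(unname(f["sre"]), (1 / 9 + 1 / 4 + 1) / 3, tolerance = 1e-12)
  expect_equal(unname(f["lre"]), 14 / 3, tolerance = 1e-12)
  expect_equal(unname(f["gln"]), 1)
  expect_equal(unname(f["rln"]), 1)
  expect_equal(unname(f["rp"]), 0.5)
  expect_equal(unname(f["lgre"]), (1 + 1 / 4 + 1 / 9) / 3, tolerance = 1e-12)
  expect_equal(unname(f["hgre"]), 14 / 3, tolerance = 1e-12)
  # single run of length N
  for (N in c(4, 9)) {
    r1 <- build_glrlm(matrix(1L, 1, N), matrix(TRUE, 1, N), 0)
    f1 <- glrlm_features(r1)
    expect_equal(unname(f1["sre"]), 1 / N^2)
    expect_equal(unname(f1["lre"]), N^2)
    expect_equal(unname(f1["rp"]), 1 / N)
  }
  # all runs length 1: SRE = LRE = 1
  cb <- matrix(rep(c(1L, 2L), 8), 4, 4); cb[, c(2, 4)] <- 3L - cb[, c(2, 4)]
  fcb <- glrlm_features(build_glrlm(cb, matrix(TRUE, 4, 4), 0))
  expect_equal(unname(fcb["sre"]), 1)
  expect_equal(unname(fcb["lre"]), 1)
  # empty matrix flagged
  f0 <- glrlm_features(build_glrlm(matrix(0L, 2, 2), matrix(FALSE, 2, 2), 0))
  expect_true(attr(f0, "no_runs"))
  expect_true(all(f0 == 0))
})

test_that("builders equal brute-force enumerators on random masked images", {
  set.seed(42)
  for (i in 1:40) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    li <- matrix(sample(1:8, nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
    if (!any(mask)) mask[1, 1] <- TRUE
    li[!mask] <- 0L
    for (a in c(0, 45, 90, 135)) {
      expect_equal(build_glcm(li, mask, a)$counts, brute_glcm(li, mask, a),
                   tolerance = 1e-12)
      pb <- brute_glrlm(li, mask, a)
      pf <- build_glrlm(li, mask, a)$p
      k <- max(ncol(pb), ncol(pf))
      pad <- function(p) cbind(p, matrix(0, nrow(p), k - ncol(p)))
      expect_equal(pad(pf), pad(pb), tolerance = 1e-12)
    }
  }
})

test_that("run lengths conserve the masked pixel count", {
  set.seed(7)
  for (i in 1:10) {
    li <- matrix(sample(1:8, 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) < 0.7, 8, 8)
    li[!mask] <- 0L
    for (a in c(0, 45, 90, 135)) {
      rl <- build_glrlm(li, mask, a)
      expect_equal(sum(rl$p %*% seq_len(ncol(rl$p))), sum(mask))
    }
  }
})

test_that("angle averaging returns the 17 features in fixed order", {
  set.seed(5)
  g <- matrix(runif(900, 0, 255), 30, 30)
  reg <- make_region(disk_mask(12, 30), gray = g,
                     rgb = flat_cell_crop(disk_mask(12, 30)))
  f <- angle_averaged_features(reg)
  expect_length(f, 17)
  expect_equal(names(f)[1:6],
               paste0("glcm_", c("max_probability", "correlation", "contrast",
                                 "energy", "homogeneity", "entropy")))
  expect_equal(names(f)[7:17],
               paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre",
                                  "hgre", "srlge", "srhge", "lrlge", "lrhge")))
  # constant cell: all four angles identical, mean equals single-angle value
  regc <- make_region(disk_mask(8, 21), gray = matrix(100, 21, 21))
  fc <- angle_averaged_features(regc)
  li <- quantize_levels(regc$gray_crop, regc$filled_mask, 8)
  single <- glcm_features(build_glcm(li, regc$filled_mask, 0))
  expect_equal(unname(fc["glcm_energy"]), unname(single["energy"]))
})

test_that("isotropic noise gives nearly isotropic GLCM contrast", {
  set.seed(99)
  g <- matrix(runif(3600, 0, 255), 60, 60)
  m <- matrix(TRUE, 60, 60)
  li <- quantize_levels(g, m, 8)
  con <- vapply(c(0, 45, 90, 135), function(a)
    glcm_features(build_glcm(li, m, a))[["contrast"]], 0)
  expect_lt(max(con) / min(con), 1.15)
})
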