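two_gaussians <- function(n1, n2, d = 2, sep = 4, seed = 11) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * d), n1, d),
             matrix(rnorm(n2 * d), n2, d) + c(rep(sep, n2), rep(0, n2 * (d - 1))))
  list(x = x, y = c(rep("a", n1), rep("b", n2)))
}

test_that("balanced input generates zero synthetic rows", {
  g <- two_gaussians(50, 50)
  out <- adasyn_balance(g$x, g$y, seed = 1)
  expect_equal(nrow(out$x), 100)
  expect_true(all(out$provenance == "original"))
})

test_that("ADASYN balances a 100-vs-20 problem into [95, 105]", {
  g <- two_gaussians(100, 20, seed = 11)
  out <- adasyn_balance(g$x, g$y, seed = 11)
  n_min <- sum(out$y == "b")
  expect_gte(n_min, 95); expect_lte(n_min, 105)
  # originals pass through untouched, in order
  expect_identical(out$x[1:120, ], unname(g$x))
  expect_identical(out$y[1:120], g$y)
  expect_true(all(out$provenance[1:120] == "original"))
  expect_true(all(out$provenance[-(1:120)] == "synthetic"))
})

test_that("synthetic rows lie on segments between same-class originals", {
  g <- two_gaussians(60, 15, sep = 3, seed = 4)
  out <- adasyn_balance(g$x, g$y, seed = 4)
  syn <- out$x[out$provenance == "synthetic", , drop = FALSE]
  orig_b <- g$x[g$y == "b", , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    s <- syn[i, ]
    on_segment <- FALSE
    for (a in seq_len(nrow(orig_b))) for (b in seq_len(nrow(orig_b))) {
      u <- orig_b[b, ] - orig_b[a, ]
      if (sum(u^2) == 0) next
      lam <- sum((s - orig_b[a, ]) * u) / sum(u^2)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((orig_b[a, ] + lam * u - s)^2)) < 1e-9) {
        on_segment <- TRUE; break
      }
    }
    expect_true(on_segment)
  }
  expect_true(all(out$y[out$provenance == "synthetic"] == "b"))
})

test_that("ADASYN is deterministic under a fixed seed and balances separated classes", {
  # classes far apart: no minority point has foreign neighbours, the uniform
  # fallback must still reach balance
  g <- two_gaussians(100, 20, sep = 50, seed = 2)
  o1 <- adasyn_balance(g$x, g$y, seed = 9)
  o2 <- adasyn_balance(g$x, g$y, seed = 9)
  expect_identical(o1, o2)
  expect_equal(sum(o1$y == "b"), 100)
  o3 <- adasyn_balance(g$x, g$y, seed = 10)
  expect_false(identical(o1$x, o3$x))
})

test_that("a class smaller than the neighbourhood is refused with guidance", {
  g <- two_gaussians(50, 4, seed = 3)
  expect_error(adasyn_balance(g$x, g$y, k_neighbors = 5), "k_neighbors")
})

test_that("LSDA recovers a separation axis", {
  set.seed(2)
  n <- 80
  x <- rbind(matrix(rnorm(n * 5), n, 5),
             matrix(rnorm(n * 5), n, 5) + c(rep(6, n), rep(0, 4 * n)))
  y <- rep(c("a", "b"), each = n)
  proj <- lsda_fit(x, y, k = 5, r = 1)
  v <- proj$projection[, 1]
  cosang <- abs(v[1]) / sqrt(sum(v^2))
  expect_gt(cosang, 0.9)                     # within ~25 degrees of axis 1
})

test_that("LSDA on 1-D data is the identity up to scale", {
  set.seed(6)
  x <- matrix(c(rnorm(30), rnorm(30) + 4), ncol = 1)
  y <- rep(c("a", "b"), each = 30)
  proj <- lsda_fit(x, y, k = 3, r = 1)
  expect_equal(ncol(proj$projection), 1)
  expect_true(abs(proj$projection[1, 1]) > 0)
  z <- lsda_transform(proj, x)
  expect_equal(cor(z[, 1], x[, 1]), 1, tolerance = 1e-12)
})

test_that("transform is linear, deterministic and rank-bounded", {
  set.seed(12)
  x <- matrix(rnorm(100 * 6), 100, 6)
  y <- rep(c("a", "b"), 50)
  proj <- lsda_fit(x, y, k = 5, r = 2)
  expect_true(all(lsda_transform(proj, matrix(0, 3, 6)) == 0))
  a <- matrix(rnorm(12), 2, 6); b <- matrix(rnorm(12), 2, 6)
  expect_equal(lsda_transform(proj, a + b),
               lsda_transform(proj, a) + lsda_transform(proj, b), tolerance = 1e-12)
  expect_equal(qr(lsda_transform(proj, x))$rank, 2)
  expect_error(lsda_transform(proj, matrix(0, 2, 5)), "dimension")
})

test_that("the LSDA objective beats random directions", {
  set.seed(20)
  n <- 60
  x <- rbind(matrix(rnorm(n * 5), n, 5),
             matrix(rnorm(n * 5), n, 5) + c(rep(4, n), rep(0, 4 * n)))
  y <- rep(c("a", "b"), each = n)
  proj <- lsda_fit(x, y, k = 5, r = 1)
  # the fitted local-margin criterion itself: between-Laplacian-plus-within-
  # affinity scatter over within-degree inertia, from the same k-NN graph
  d <- as.matrix(dist(x)); diag(d) <- Inf
  nn <- t(apply(d, 1, function(rr) order(rr)[1:5]))
  A <- matrix(0, 2 * n, 2 * n)
  A[cbind(rep(seq_len(2 * n), 5), as.vector(nn))] <- 1
  A <- pmax(A, t(A))
  same <- outer(y, y, "==")
  Ww <- A * same; Wb <- A * !same
  M <- 0.5 * (diag(rowSums(Wb)) - Wb) + 0.5 * Ww
  Dw <- diag(rowSums(Ww))
  objective <- function(v) {
    z <- x %*% v
    drop(crossprod(z, M %*% z) / crossprod(z, Dw %*% z))
  }
  obj_lsda <- objective(proj$projection)
  set.seed(21)
  wins <- 0
  for (i in 1:20) {
    v <- matrix(rnorm(5)); v <- v / sqrt(sum(v^2))
    if (obj_lsda >= objective(v)) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("class-scrambled labels give no discriminative projection", {
  set.seed(30)
  n <- 60
  x <- rbind(matrix(rnorm(n * 5), n, 5),
             matrix(rnorm(n * 5), n, 5) + c(rep(5, n), rep(0, 4 * n)))
  y_true <- rep(c("a", "b"), each = n)
  y_scr <- sample(y_true)
  fisher <- function(z, y) {
    za <- z[y == "a"]; zb <- z[y == "b"]
    (mean(za) - mean(zb))^2 / (var(za) + var(zb))
  }
  proj <- lsda_fit(x, y_scr, k = 5, r = 1)
  f_proj <- fisher(lsda_transform(proj, x)[, 1], y_scr)
  f_best_axis <- max(vapply(1:5, function(j) fisher(x[, j], y_scr), 0))
  expect_lt(f_proj, f_best_axis + 0.15)
})

test_that("LSDA improves silhouette on separable classes", {
  skip_if_not_installed("cluster")
  set.seed(40)
  n <- 70
  x <- rbind(matrix(rnorm(n * 5), n, 5),
             matrix(rnorm(n * 5), n, 5) + c(rep(5, n), rep(0, 4 * n)))
  y <- rep(1:2, each = n)
  proj <- lsda_fit(x, as.character(y), k = 5, r = 1)
  z <- lsda_transform(proj, x)
  sil_before <- mean(cluster::silhouette(y, dist(x))[, 3])
  sil_after <- mean(cluster::silhouette(y, dist(z))[, 3])
  expect_gte(sil_after, sil_before)
})
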