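## Class balancing (ADASYN) and supervised dimensionality reduction (LSDA)
## for the per-cell feature table.

# column standardization helpers (fit on training data, apply anywhere)
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(center = mu, scale = sd)
}
standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$center), 2, st$scale, "/")
}

#' Adaptive synthetic oversampling (ADASYN)
#'
#' Balances every minority class up to the majority-class count by generating
#' synthetic rows.  For each minority point the generation budget is
#' proportional to the fraction of its `k_neighbors` nearest neighbours that
#' belong to other classes, so generation concentrates near class boundaries
#' where the classifier needs support; each synthetic row is a convex
#' interpolation between the point and one of its same-class neighbours.
#' When a minority class is so well separated that no point has any
#' foreign neighbour, the budget is spread uniformly so the balancing
#' contract still holds.
#'
#' Original rows are never modified or removed.
#'
#' @param x Numeric matrix (rows = cells, columns = features).
#' @param y Class labels (factor or character), length `nrow(x)`.
#' @param k_neighbors Neighbourhood size (default 5).
#' @param balance_tol Acceptable relative deviation from the majority count
#'   (the exact apportionment used here achieves 0).
#' @param seed Integer seed.
#' @return List with `x`, `y`, and `provenance` (`"original"`/`"synthetic"`).
#' @export
adasyn_balance <- function(x, y, k_neighbors = 5, balance_tol = 0.05, seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  counts <- table(y)
  n_major <- max(counts)
  minority <- names(counts)[counts < n_major]
  too_small <- names(counts)[counts < k_neighbors + 1 & names(counts) %in% minority]
  if (length(too_small))
    stop("class(es) ", paste(too_small, collapse = ", "), " have fewer than ",
         k_neighbors + 1, " members; lower k_neighbors or provide more data")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  new_x <- list(); new_y <- character()
  for (cls in minority) {
    idx <- which(y == cls)
    G <- n_major - length(idx)
    if (G <= 0) next
    nn <- t(apply(d[idx, , drop = FALSE], 1, function(r) order(r)[seq_len(k_neighbors)]))
    r_i <- rowMeans(matrix(y[nn] != cls, nrow(nn), ncol(nn)))
    w <- if (sum(r_i) > 0) r_i / sum(r_i) else rep(1 / length(idx), length(idx))
    # exact apportionment: floors plus largest remainders
    g <- floor(w * G)
    rem <- G - sum(g)
    if (rem > 0) {
      extra <- order(w * G - g, decreasing = TRUE)[seq_len(rem)]
      g[extra] <- g[extra] + 1L
    }
    # same-class neighbours for interpolation
    d_cls <- d[idx, idx, drop = FALSE]
    for (ii in seq_along(idx)) {
      if (g[ii] == 0) next
      nbr <- order(d_cls[ii, ])[seq_len(min(k_neighbors, length(idx) - 1))]
      pick <- nbr[sample.int(length(nbr), g[ii], replace = TRUE)]
      lam <- stats::runif(g[ii])
      base <- x[idx[ii], ]
      for (jj in seq_len(g[ii])) {
        new_x[[length(new_x) + 1L]] <-
          base + lam[jj] * (x[idx[pick[jj]], ] - base)
        new_y <- c(new_y, cls)
      }
    }
  }
  if (length(new_x)) {
    xs <- do.call(rbind, new_x)
    colnames(xs) <- colnames(x)
    list(x = rbind(x, xs), y = c(y, new_y),
         provenance = c(rep("original", nrow(x)), rep("synthetic", nrow(xs))))
  } else {
    list(x = x, y = y, provenance = rep("original", nrow(x)))
  }
}

#' Fit a locality sensitive discriminant analysis (LSDA) projection
#'
#' Builds a k-nearest-neighbour graph, splits its edges into within-class and
#' between-class sets, and finds linear directions that push locally
#' neighbouring points of *different* classes apart while keeping locally
#' neighbouring points of the *same* class close.  The directions solve the
#' generalized eigenproblem
#' `X' (alpha Lb + (1 - alpha) Ww) X a = lambda X' Dw X a`
#' where `Ww`/`Wb` are the within/between adjacency matrices, `Lb = Db - Wb`
#' the between-class graph Laplacian and `Dw` the within-class degree matrix;
#' a ridge term regularizes the right-hand side.
#'
#' @param x Numeric matrix (rows = observations); standardize beforehand if
#'   columns have incomparable scales.
#' @param y Class labels.
#' @param k Neighbourhood size (default 5).
#' @param r Reduced dimension; default `nlevels - 1`.
#' @param regularization Ridge coefficient on the constraint matrix.
#' @param alpha Trade-off between the between-class margin and within-class
#'   compactness terms (default 0.5).
#' @return Object of class `"lsda"`: `projection` (d x r, eigenvector
#'   columns, largest-magnitude component positive), `eigenvalues`, `k`, `r`.
#' @export
lsda_fit <- function(x, y, k = 5, r = NULL, regularization = 1e-3, alpha = 0.5) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x); dd <- ncol(x)
  if (is.null(r)) r <- max(1L, length(unique(y)) - 1L)
  stopifnot(r <= dd, n > k)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(rr) order(rr)[seq_len(k)]))
  A <- matrix(0, n, n)
  A[cbind(rep(seq_len(n), k), as.vector(nn))] <- 1
  A <- pmax(A, t(A))                    # symmetric neighbour relation
  same <- outer(y, y, "==")
  Ww <- A * same
  Wb <- A * !same
  Dw <- diag(rowSums(Ww))
  Lb <- diag(rowSums(Wb)) - Wb
  M <- alpha * Lb + (1 - alpha) * Ww
  S <- crossprod(x, M %*% x)
  S <- (S + t(S)) / 2
  C <- crossprod(x, Dw %*% x)
  C <- (C + t(C)) / 2 + regularization * mean(diag(crossprod(x))) / dd * diag(dd)
  R <- tryCatch(chol(C), error = function(e)
    stop("constraint matrix is singular despite regularization ",
         "(condition estimate ", format(kappa(C), digits = 3), ")"))
  Rt_inv <- backsolve(R, diag(dd), transpose = TRUE)
  Sy <- Rt_inv %*% S %*% t(Rt_inv)
  Sy <- (Sy + t(Sy)) / 2
  eig <- eigen(Sy, symmetric = TRUE)
  W <- backsolve(R, eig$vectors[, seq_len(r), drop = FALSE])
  # reproducible sign: largest-magnitude component positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  colnames(W) <- paste0("lsda", seq_len(r))
  structure(list(projection = W, eigenvalues = eig$values[seq_len(r)],
                 k = k, r = r, alpha = alpha, regularization = regularization,
                 dim_in = dd),
            class = "lsda")
}

#' @export
print.lsda <- function(x, ...) {
  cat("LSDA projection:", x$dim_in, "->", x$r, "dimensions (k =", x$k,
      "); leading eigenvalues:",
      paste(format(x$eigenvalues, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Apply an LSDA projection
#'
#' @param proj An `"lsda"` object.
#' @param x Numeric matrix with the same columns the projection was fit on.
#' @return `n x r` matrix of reduced features.
#' @export
lsda_transform <- function(proj, x) {
  stopifnot(inherits(proj, "lsda"))
  x <- as.matrix(x)
  if (ncol(x) != proj$dim_in)
    stop("feature dimension ", ncol(x), " does not match projection input ",
         proj$dim_in)
  x %*% proj$projection
}

#' @export
predict.lsda <- function(object, newdata, ...) lsda_transform(object, newdata)
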