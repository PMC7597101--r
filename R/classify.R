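## Random-forest + multilayer-perceptron soft-voting ensemble and the
## cross-validated evaluation harness.

#' Train the RF + MLP ensemble
#'
#' Fits a random forest and a single-hidden-layer perceptron (softmax output,
#' weight-decay regularization) on the same rows; predictions average the two
#' class-probability vectors with equal weight (soft vote) or take a
#' majority between the two argmax labels (hard vote).
#'
#' @param x Numeric matrix of features.
#' @param y Class labels (coerced to factor).
#' @param rf_trees Number of forest trees (default 200).
#' @param mlp_hidden Hidden units (default 64).
#' @param epochs Maximum optimizer iterations for the MLP (default 200).
#' @param mlp_decay Weight decay (default 1e-3).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return Object of class `"rbc_ensemble"`.
#' @export
rbc_ensemble <- function(x, y, rf_trees = 200, mlp_hidden = 64, epochs = 200,
                         mlp_decay = 1e-3, seed = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("training needs at least two classes")
  small <- table(y) < 10
  if (any(small))
    warning("class(es) with fewer than 10 rows: ",
            paste(names(which(small)), collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  rf <- randomForest::randomForest(x, y, ntree = rf_trees)
  targets <- nnet::class.ind(y)
  mlp <- nnet::nnet(x, targets, size = mlp_hidden, softmax = TRUE,
                    decay = mlp_decay, maxit = epochs,
                    MaxNWts = 100000, trace = FALSE)
  structure(list(rf = rf, mlp = mlp, levels = levels(y),
                 config = list(rf_trees = rf_trees, mlp_hidden = mlp_hidden,
                               epochs = epochs, mlp_decay = mlp_decay,
                               seed = seed)),
            class = "rbc_ensemble")
}

#' @export
print.rbc_ensemble <- function(x, ...) {
  cat("RBC classification ensemble (soft vote):\n",
      " random forest:", x$config$rf_trees, "trees\n",
      " perceptron:", x$config$mlp_hidden, "hidden units, decay",
      x$config$mlp_decay, "\n  classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict with the ensemble
#'
#' @param object An `"rbc_ensemble"`.
#' @param newdata Feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param vote `"soft"` (average probabilities; default) or `"hard"`.
#' @param ... Unused.
#' @return Factor of predicted classes or a probability matrix.
#' @export
predict.rbc_ensemble <- function(object, newdata, type = c("class", "prob"),
                                 vote = c("soft", "hard"), ...) {
  type <- match.arg(type); vote <- match.arg(vote)
  newdata <- as.matrix(newdata)
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  p_rf <- stats::predict(object$rf, newdata, type = "prob")
  p_mlp <- stats::predict(object$mlp, newdata)
  p_mlp <- p_mlp[, object$levels, drop = FALSE]
  p <- (p_rf[, object$levels, drop = FALSE] + p_mlp) / 2
  if (type == "prob") return(p)
  cls <- if (vote == "soft") {
    object$levels[max.col(p, ties.method = "first")]
  } else {
    a <- object$levels[max.col(p_rf[, object$levels, drop = FALSE], ties.method = "first")]
    b <- object$levels[max.col(p_mlp, ties.method = "first")]
    # tie between the two voters broken by the higher combined probability
    ifelse(a == b, a, object$levels[max.col(p, ties.method = "first")])
  }
  factor(cls, levels = object$levels)
}

#' Classification report from truth and prediction
#'
#' One-vs-rest confusion counts per class with precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, F1 (harmonic mean) and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`; macro averages over the classes, plus overall
#' (multi-class) accuracy.  Metrics undefined for a class with no positive
#' predictions/instances are `NA` and excluded from the macro mean (with a
#' note in `$undefined`).
#'
#' @param truth,prediction Vectors of equal length.
#' @return Object of class `"classification_report"`.
#' @export
classification_report <- function(truth, prediction) {
  truth <- as.character(truth); prediction <- as.character(prediction)
  stopifnot(length(truth) == length(prediction))
  classes <- sort(unique(c(truth, prediction)))
  n <- length(truth)
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & prediction == cl)
    fp <- sum(truth != cl & prediction == cl)
    fn <- sum(truth == cl & prediction != cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    list(TP = tp, FP = fp, FN = fn, TN = tn, precision = prec, recall = rec,
         f1 = f1, accuracy = (tp + tn) / n, support = sum(truth == cl))
  })
  names(per) <- classes
  macro <- function(field) {
    v <- vapply(per, `[[`, 0, field)
    mean(v, na.rm = TRUE)
  }
  undefined <- classes[vapply(per, function(p)
    anyNA(c(p$precision, p$recall, p$f1)), TRUE)]
  cm <- table(factor(truth, classes), factor(prediction, classes))
  structure(list(per_class = per,
                 macro = list(precision = macro("precision"),
                              recall = macro("recall"),
                              f1 = macro("f1"),
                              accuracy = macro("accuracy")),
                 accuracy = sum(diag(cm)) / n,
                 confusion = cm,
                 n = n,
                 undefined = undefined),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 3, ...) {
  cat("Classification report (", x$n, " cells)\n", sep = "")
  tab <- do.call(rbind, lapply(x$per_class, function(p)
    c(precision = p$precision, recall = p$recall, f1 = p$f1,
      support = p$support)))
  print(round(tab, digits))
  cat(sprintf("macro: precision %.3f | recall %.3f | F1 %.3f\noverall accuracy %.3f\n",
              x$macro$precision, x$macro$recall, x$macro$f1, x$accuracy))
  if (length(x$undefined))
    cat("metrics undefined (excluded from macro) for:",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  out <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

#' Cross-validated evaluation of the full training pipeline
#'
#' Stratified k-fold cross-validation in which every training-only step --
#' feature standardization, ADASYN balancing and LSDA reduction -- is fit
#' inside each training fold and merely applied to the held-out fold, so no
#' synthetic row and no statistic of the test data ever leaks into training.
#'
#' @param x Feature matrix (original cells only).
#' @param y Class labels.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment, ADASYN and training.
#' @param adasyn Balance training folds with [adasyn_balance()] (default TRUE).
#' @param lsda_r Reduced dimension; default classes - 1; `NA` skips LSDA.
#' @param k_neighbors Neighbourhood size for ADASYN/LSDA graphs.
#' @param ... Passed to [rbc_ensemble()].
#' @return A `"classification_report"` with extra fields `folds` (assignment)
#'   and `test_provenance` (always `"original"`; the leak check).
#' @export
cross_validate <- function(x, y, folds = 5, seed = 1, adasyn = TRUE,
                           lsda_r = NULL, k_neighbors = 5, ...) {
  x <- as.matrix(x); y <- as.character(y)
  stopifnot(folds >= 2, nrow(x) == length(y))
  fold_id <- stratified_folds(y, folds, seed)
  pred <- character(length(y))
  prov <- character(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    st <- standardize_fit(x[tr, , drop = FALSE])
    xtr <- standardize_apply(x[tr, , drop = FALSE], st)
    xte <- standardize_apply(x[te, , drop = FALSE], st)
    ytr <- y[tr]
    if (adasyn) {
      bal <- adasyn_balance(xtr, ytr, k_neighbors = k_neighbors,
                            seed = seed + f)
      xtr <- bal$x; ytr <- bal$y
    }
    r <- if (is.null(lsda_r)) max(1L, length(unique(y)) - 1L) else lsda_r
    if (!is.na(r)) {
      proj <- lsda_fit(xtr, ytr, k = k_neighbors, r = r)
      xtr <- lsda_transform(proj, xtr)
      xte <- lsda_transform(proj, xte)
    }
    model <- rbc_ensemble(xtr, ytr, seed = seed + f, ...)
    pred[te] <- as.character(predict(model, xte))
    prov[te] <- "original"
  }
  rep <- classification_report(y, pred)
  rep$folds <- fold_id
  rep$test_provenance <- prov
  rep$seed <- seed
  rep
}
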