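#' Train an MTU classifier
#'
#' Default method `"centroid"`: nearest centroid on cosine distance — bin
#' intensity rows are scaled to unit norm, class centroids are the means of
#' the unit rows, and prediction assigns the class with the highest cosine
#' to its centroid. Deterministic and tuning-free. Alternative `"tree"`
#' fits a small CART-style decision tree (binary Gini splits on single bins,
#' grown to purity; no pruning), useful when single marker peaks separate
#' the classes.
#'
#' Training requires every class to have at least 2 members: singleton MTUs
#' must be discarded before training.
#'
#' @param fm a [feature_matrix()] restricted to replicated MTUs (plus any
#'   reference classes such as BTS).
#' @param labels class label (e.g. `mtu_id`) per feature-matrix row.
#' @param method `"centroid"` or `"tree"`.
#' @param min_class_size smallest admissible class (default 2; leave-one-out
#'   folds relax this to 1 internally).
#' @return object of class `mtu_classifier`.
#' @export
train_classifier <- function(fm, labels, method = c("centroid", "tree"),
                             min_class_size = 2) {
  method <- match.arg(method)
  labels <- as.character(labels)
  if (length(labels) != nrow(fm$intensity))
    stop("labels must match feature-matrix rows", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < min_class_size))
    stop("classes with a single member: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         "; discard singleton MTUs before training", call. = FALSE)
  X <- unit_rows(fm$intensity)
  model <- if (method == "centroid") {
    cls <- sort(unique(labels))
    cen <- t(vapply(cls, function(k)
      colMeans(X[labels == k, , drop = FALSE]), numeric(ncol(X))))
    list(classes = cls, centroids = unit_rows(cen))
  } else {
    list(fit = grow_tree(X, labels, depth = 0L),
         classes = sort(unique(labels)))
  }
  structure(list(method = method, model = model, bin_mz = fm$bin_mz,
                 n_bins = ncol(fm$intensity)),
            class = "mtu_classifier")
}

unit_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

#' @export
print.mtu_classifier <- function(x, ...) {
  cat(sprintf("<mtu_classifier> %s over %d bins, %d classes\n",
              x$method, x$n_bins, length(x$model$classes)))
  invisible(x)
}

#' @param object an `mtu_classifier`.
#' @param fm feature matrix of spectra to classify (same bins as training).
#' @param ... unused.
#' @rdname train_classifier
#' @export
predict.mtu_classifier <- function(object, fm, ...) {
  X <- unit_rows(fm$intensity)
  if (ncol(X) != object$n_bins)
    stop("feature matrix has ", ncol(X), " bins; classifier expects ",
         object$n_bins, call. = FALSE)
  if (object$method == "centroid") {
    scores <- tcrossprod(X, object$model$centroids)
    object$model$classes[max.col(scores, ties.method = "first")]
  } else {
    vapply(seq_len(nrow(X)), function(i)
      tree_predict(object$model$fit, X[i, ]), "")
  }
}

# --- minimal CART: binary Gini splits on one bin at a time, grown to purity

gini <- function(y) 1 - sum((table(y) / length(y))^2)

grow_tree <- function(X, y, depth, max_depth = 25L) {
  majority <- names(sort(table(y), decreasing = TRUE))[1]
  if (length(unique(y)) == 1L || depth >= max_depth || nrow(X) < 2L)
    return(list(leaf = TRUE, class = majority))
  n <- length(y)
  best <- list(gain = 0)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    u <- sort(unique(v))
    if (length(u) < 2) next
    for (t in (u[-1] + u[-length(u)]) / 2) {
      l <- v <= t
      gain <- gini(y) - (sum(l) * gini(y[l]) + sum(!l) * gini(y[!l])) / n
      if (gain > best$gain + 1e-12)
        best <- list(gain = gain, j = j, t = t)
    }
  }
  if (best$gain <= 0) return(list(leaf = TRUE, class = majority))
  l <- X[, best$j] <= best$t
  list(leaf = FALSE, j = best$j, t = best$t,
       left = grow_tree(X[l, , drop = FALSE], y[l], depth + 1L, max_depth),
       right = grow_tree(X[!l, , drop = FALSE], y[!l], depth + 1L, max_depth))
}

tree_predict <- function(node, x) {
  while (!node$leaf) node <- if (x[node$j] <= node$t) node$left else node$right
  node$class
}

#' Evaluate an MTU classifier
#'
#' `"resubstitution"` predicts the training rows with the supplied model;
#' `"loo"` refits without each row in turn (leave-one-out). Reports the
#' confusion matrix (true x predicted), accuracy and Cohen's kappa.
#' Predictions of a class absent from the true labels land in an extra
#' reject column and are flagged.
#'
#' @param model an `mtu_classifier` (ignored under `"loo"`, which refits).
#' @param fm feature matrix.
#' @param labels true class per row.
#' @param scheme `"resubstitution"` or `"loo"`.
#' @return list of class `classifier_report`: `confusion`, `accuracy`,
#'   `kappa`, `n_classes`, `n_items`, `scheme`.
#' @export
evaluate_classifier <- function(model, fm, labels,
                                scheme = c("resubstitution", "loo")) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  pred <- if (scheme == "resubstitution") predict(model, fm)
  else vapply(seq_along(labels), function(i) {
    sub <- feature_matrix(fm$bin_mz, fm$spectrum_ids[-i],
                          fm$intensity[-i, , drop = FALSE])
    m <- train_classifier(sub, labels[-i], method = model$method,
                          min_class_size = 1)
    one <- feature_matrix(fm$bin_mz, fm$spectrum_ids[i],
                          fm$intensity[i, , drop = FALSE])
    predict(m, one)
  }, "")
  cls <- sort(unique(labels))
  rejected <- !(pred %in% cls)
  lev <- c(cls, if (any(rejected)) ".reject")
  pred2 <- ifelse(rejected, ".reject", pred)
  confusion <- table(factor(labels, levels = lev),
                     factor(pred2, levels = lev))
  k <- cohen_kappa(confusion)
  structure(list(confusion = unclass(confusion),
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 kappa = k, n_classes = length(cls),
                 n_items = length(labels), scheme = scheme,
                 rejected = sum(rejected)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %s: %d items, %d classes, accuracy %.3f, kappa %.3f\n",
    x$scheme, x$n_items, x$n_classes, x$accuracy, x$kappa))
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o =
#' trace/N` and chance agreement `p_e = sum_k row_k * col_k / N^2`. When
#' `p_e == 1`, kappa is 1 if agreement is perfect and undefined (error)
#' otherwise. Ranges over \[-1, 1\].
#'
#' @param confusion square non-negative count matrix (true x predicted).
#' @return scalar kappa.
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  N <- sum(m)
  if (N <= 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(m)) / N
  pe <- sum(rowSums(m) * colSums(m)) / N^2
  if (pe >= 1) {
    if (po == 1) return(1)
    stop("kappa undefined: chance agreement is 1 with imperfect agreement",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}
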