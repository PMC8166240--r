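#' Pairwise Jaccard similarity of peak presence sets
#'
#' `J[i, j] = |bins shared| / |bins in union|` over the binary presence mask
#' of a feature matrix. Pairs with an empty union are set to 0 and recorded
#' in `attr(, "empty_union")`.
#'
#' @param fm a [feature_matrix()] with at least 2 spectra.
#' @return symmetric matrix in \[0, 1\] with unit diagonal, dimnames set to
#'   the spectrum ids.
#' @export
jaccard_matrix <- function(fm) {
  P <- fm$presence * 1
  if (nrow(P) < 2) stop("need >= 2 spectra", call. = FALSE)
  shared <- tcrossprod(P)
  sizes <- rowSums(P)
  union <- outer(sizes, sizes, `+`) - shared
  J <- ifelse(union > 0, shared / union, 0)
  diag(J) <- 1
  dimnames(J) <- list(fm$spectrum_ids, fm$spectrum_ids)
  attr(J, "empty_union") <- which(union == 0 & upper.tri(union), arr.ind = TRUE)
  J
}

#' Pairwise cosine similarity of binned intensity vectors
#'
#' `C[i, j] = <a, b> / (||a|| ||b||)` over the bin intensities. Rows with a
#' zero vector give 0 against everything (flagged in `attr(, "zero_rows")`);
#' diagonal is reset to 1.
#'
#' @inheritParams jaccard_matrix
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
cosine_matrix <- function(fm) {
  X <- fm$intensity
  if (nrow(X) < 2) stop("need >= 2 spectra", call. = FALSE)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  C <- tcrossprod(X / nrm)
  C[zero, ] <- 0; C[, zero] <- 0
  C <- pmin(pmax(C, 0), 1)
  diag(C) <- 1
  dimnames(C) <- list(fm$spectrum_ids, fm$spectrum_ids)
  attr(C, "zero_rows") <- which(zero)
  C
}

#' Fit the hyperbolic Jaccard-to-cosine model
#'
#' Spectra sharing almost no peaks still show substantial cosine similarity
#' because of peak-height variability. The model
#' `y_hat(x) = y0 + x / (x + 0.2)` (x = Jaccard coefficient) captures this:
#' `y0` is the average cosine similarity of pairs with Jaccard near zero and
#' the hyperbolic term saturates with constant 0.2. `y0` is estimated as the
#' mean cosine over pairs with `J < epsilon`; if fewer than 10 such pairs
#' exist, the lowest decile of J is used instead (with a warning).
#'
#' @param J,C Jaccard and cosine similarity matrices (same shape).
#' @param epsilon Jaccard cutoff defining "near zero" (default 0.05).
#' @return an object of class `hyperbolic_model` with fields `y0`,
#'   `saturation` (fixed 0.2), `n_pairs`.
#' @export
fit_hyperbolic <- function(J, C, epsilon = 0.05) {
  if (!all(dim(J) == dim(C))) stop("J and C shapes differ", call. = FALSE)
  ut <- upper.tri(J)
  low <- ut & (J < epsilon)
  if (sum(low) < 10) {
    warning("fewer than 10 pairs with J < ", epsilon,
            "; using the lowest decile of J for y0")
    cut <- quantile(J[ut], 0.1)
    low <- ut & (J <= cut)
  }
  y0 <- mean(C[low])
  structure(list(y0 = y0, saturation = 0.2, n_pairs = sum(low)),
            class = "hyperbolic_model")
}

#' @export
print.hyperbolic_model <- function(x, ...) {
  cat(sprintf("<hyperbolic_model> y_hat(x) = %.4f + x/(x + %.1f)  (y0 from %d pairs)\n",
              x$y0, x$saturation, x$n_pairs))
  invisible(x)
}

#' @param object a `hyperbolic_model`.
#' @param x Jaccard coefficients.
#' @param ... unused.
#' @rdname fit_hyperbolic
#' @export
predict.hyperbolic_model <- function(object, x, ...) {
  object$y0 + x / (x + object$saturation)
}

#' Weight cosine similarities by the Jaccard-predicted factor
#'
#' Down-weights cosine similarity between spectra that share few peaks:
#' `W = C * clamp(y_hat(J), 0, 1)` under the default `"multiply"` combiner
#' (alternatives: elementwise `"min"`, `"geometric_mean"`). The result is
#' clipped to \[0, 1\] and the diagonal reset to 1.
#'
#' @param C cosine matrix.
#' @param J Jaccard matrix, same shape.
#' @param model a fitted [fit_hyperbolic()] model.
#' @param combiner how to combine `C` with the clamped prediction.
#' @return weighted similarity matrix in \[0, 1\].
#' @export
weight_cosine <- function(C, J, model,
                          combiner = c("multiply", "min", "geometric_mean")) {
  combiner <- match.arg(combiner)
  if (!all(dim(C) == dim(J))) stop("C and J shapes differ", call. = FALSE)
  f <- pmin(pmax(predict(model, J), 0), 1)
  W <- switch(combiner,
              multiply = C * f,
              min = pmin(C, f),
              geometric_mean = sqrt(C * f))
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 1
  dimnames(W) <- dimnames(C)
  W
}

#' Jaccard, cosine and weighted similarity in one call
#'
#' @inheritParams jaccard_matrix
#' @inheritParams weight_cosine
#' @param epsilon passed to [fit_hyperbolic()].
#' @return list with elements `jaccard`, `cosine`, `model`, `weighted`.
#' @export
similarity_bundle <- function(fm, epsilon = 0.05,
                              combiner = c("multiply", "min", "geometric_mean")) {
  J <- jaccard_matrix(fm)
  C <- cosine_matrix(fm)
  model <- fit_hyperbolic(J, C, epsilon)
  W <- weight_cosine(C, J, model, match.arg(combiner))
  list(jaccard = J, cosine = C, model = model, weighted = W)
}
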