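#' Four-parameter logistic fit of 16S identity against weighted cosine
#'
#' Fits `identity = lower + (upper - lower) / (1 + exp((midpoint - w) /
#' scale))` by nonlinear least squares (self-starting initialization from
#' data quantiles). The midpoint, in weighted-cosine units, is where the
#' curve crosses halfway between its asymptotes and anchors the MTU
#' threshold choice.
#'
#' @param w weighted cosine similarities (one per isolate pair).
#' @param identity percent 16S identities, same length.
#' @return object of class `sigmoid_model`: `lower`, `upper`, `midpoint`,
#'   `scale`, `r_squared`, and the underlying `nls` fit.
#' @export
fit_sigmoid <- function(w, identity) {
  if (length(w) != length(identity)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(w) & is.finite(identity)
  w <- w[ok]; identity <- identity[ok]
  if (length(w) < 10) stop("need >= 10 pairs", call. = FALSE)
  if (sd(identity) == 0) stop("degenerate data: constant identity", call. = FALSE)
  df <- data.frame(x = w, y = identity)
  # scaleOffset keeps the relative-offset convergence test meaningful when
  # the fit is (near-)exact, i.e. zero residual sum of squares
  fit <- tryCatch(
    nls(y ~ SSfpl(x, A, B, xmid, scal), data = df,
        control = stats::nls.control(maxiter = 100, scaleOffset = 1)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    cf <- c(A = cf[["A"]], B = cf[["B"]], xmid = cf[["xmid"]],
            scal = cf[["scal"]])
    rss <- sum((df$y - fitted(fit))^2)
  } else {
    # sharp transitions (scal -> 0) make the gradient singular; profile the
    # nonlinear pair (xmid, scal) on a grid, solving the linear pair (A, B)
    # exactly at each node, then polish with nls if possible
    g <- profile_fpl(df$x, df$y)
    fit <- tryCatch(
      nls(y ~ A + (B - A) / (1 + exp((xmid - x) / scal)), data = df,
          start = as.list(g$par), algorithm = "port",
          lower = c(A = 0, B = 0, xmid = min(df$x), scal = -Inf),
          upper = c(A = 100, B = 100, xmid = max(df$x), scal = Inf),
          control = stats::nls.control(maxiter = 100, scaleOffset = 1,
                                       warnOnly = FALSE)),
      error = function(e) NULL)
    # keep the ridge-centered grid solution unless the polish genuinely
    # improves the fit (on tie ridges port stops at an arbitrary midpoint)
    if (!is.null(fit) &&
        sum((df$y - fitted(fit))^2) < g$rss * (1 - 1e-4)) {
      cf <- coef(fit)[c("A", "B", "xmid", "scal")]
      rss <- sum((df$y - fitted(fit))^2)
    } else {
      cf <- g$par
      rss <- g$rss
    }
  }
  if (!all(is.finite(cf)))
    stop("sigmoid fit did not converge", call. = FALSE)
  lower <- min(cf[["A"]], cf[["B"]]); upper <- max(cf[["A"]], cf[["B"]])
  r2 <- 1 - rss / sum((df$y - mean(df$y))^2)
  structure(list(lower = lower, upper = upper,
                 midpoint = unname(cf[["xmid"]]),
                 scale = unname(cf[["scal"]]),
                 increasing = (cf[["B"]] > cf[["A"]]) == (cf[["scal"]] > 0),
                 r_squared = r2, fit = fit),
            class = "sigmoid_model")
}

# grid-profiled 4PL least squares: for each (xmid, scal) node the model is
# linear in (A, B) -- solved exactly, with the percentage bounds 0 <= A, B
# <= 100 enforced by refitting on the active constraint. Two-clump identity
# data leaves the midpoint unidentified along a ridge of equal RSS; the
# midpoint returned is the center of that ridge.
profile_fpl <- function(x, y) {
  xmids <- sort(unique(quantile(x, seq(0.02, 0.98, length.out = 49),
                                names = FALSE)))
  span <- diff(range(x))
  scals <- span * c(1e-3, 2e-3, 5e-3, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4)
  scals <- c(scals, -scals)
  fit_node <- function(m, s) {
    z <- 1 / (1 + exp((m - x) / s))
    if (sd(z) < 1e-12) return(NULL)
    cf <- lm.fit(cbind(1, z), y)$coefficients
    A <- cf[1]; B <- cf[1] + cf[2]
    clamp <- function(v) min(max(v, 0), 100)
    if (A < 0 || A > 100 || B < 0 || B > 100) {
      # refit with the out-of-bounds parameter pinned to its limit
      if (B < 0 || B > 100) {
        Bc <- clamp(B)
        A <- sum((1 - z) * (y - Bc * z)) / sum((1 - z)^2)
        A <- clamp(A); B <- Bc
      } else {
        Ac <- clamp(A)
        B <- sum(z * (y - Ac * (1 - z))) / sum(z^2)
        B <- clamp(B); A <- Ac
      }
    }
    resid <- y - (A + (B - A) * z)
    list(rss = sum(resid^2),
         par = c(A = unname(A), B = unname(B), xmid = m, scal = s))
  }
  fits <- list()
  for (m in xmids) for (s in scals) {
    f <- fit_node(m, s)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("sigmoid fit did not converge", call. = FALSE)
  rss <- vapply(fits, `[[`, 0, "rss")
  ties <- which(rss <= min(rss) * (1 + 1e-6) + 1e-9)
  mids <- vapply(fits[ties], function(f) f$par[["xmid"]], 0)
  pick <- ties[which.min(abs(mids - stats::median(mids)))]
  fits[[pick]]
}

#' @param object a `sigmoid_model`.
#' @param x weighted cosine values to predict identities for.
#' @param ... unused.
#' @rdname fit_sigmoid
#' @export
predict.sigmoid_model <- function(object, x, ...) {
  a <- if (object$increasing) object$lower else object$upper
  b <- if (object$increasing) object$upper else object$lower
  a + (b - a) / (1 + exp((object$midpoint - x) / abs(object$scale)))
}

#' @export
print.sigmoid_model <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_model> asymptotes %.2f-%.2f, midpoint %.3f, scale %.4f, r2 %.3f\n",
    x$lower, x$upper, x$midpoint, x$scale, x$r_squared))
  invisible(x)
}

#' MTU threshold derived from the sigmoid midpoint
#'
#' The operating rule: round the fitted midpoint to 2 decimals and step one
#' hundredth below it, so a midpoint of 0.66 yields the working threshold
#' 0.65 (clusters are cut just under the species transition).
#'
#' @param model a [fit_sigmoid()] model.
#' @return scalar threshold in weighted-cosine units.
#' @export
threshold_from_sigmoid <- function(model) {
  round(model$midpoint, 2) - 0.01
}

#' Cluster isolates into MALDI-TOF taxonomic units
#'
#' Average-linkage (default) agglomerative clustering on the distance
#' `1 - W`, cut at height `1 - threshold`. MTU ids are integers assigned in
#' order of first appearance in the input. Counts of singleton MTUs (one
#' isolate) and replicated MTUs (more than one) are reported.
#'
#' @param W symmetric weighted-similarity matrix in \[0, 1\] with unit
#'   diagonal and spectrum-id dimnames.
#' @param threshold similarity threshold in (0, 1); default 0.65.
#' @param linkage one of `"average"`, `"complete"`, `"single"`.
#' @return list of class `mtu_result`: `table` (data.frame `spectrum_id,
#'   mtu_id`), `n_mtus`, `singletons`, `replicated`, `threshold`, `hclust`.
#' @export
cluster_mtus <- function(W, threshold = 0.65,
                         linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!isSymmetric(unname(W), tol = 1e-8))
    stop("similarity matrix must be symmetric", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  hc <- hclust(as.dist(1 - W), method = linkage)
  cl <- cutree(hc, h = 1 - threshold)
  mtu <- match(cl, unique(cl))        # renumber by first occurrence
  sizes <- table(mtu)
  structure(list(table = data.frame(spectrum_id = rownames(W), mtu_id = mtu),
                 n_mtus = length(sizes),
                 singletons = sum(sizes == 1),
                 replicated = sum(sizes > 1),
                 threshold = threshold, linkage = linkage, hclust = hc),
            class = "mtu_result")
}

#' @export
print.mtu_result <- function(x, ...) {
  cat(sprintf(
    "<mtu_result> %d isolates -> %d MTUs (%d replicated, %d singletons) at threshold %.2f (%s linkage)\n",
    nrow(x$table), x$n_mtus, x$replicated, x$singletons, x$threshold,
    x$linkage))
  invisible(x)
}

# leaf-id sets of every internal node of an hclust, as sorted key strings
clade_keys <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  keys <- character(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    ids <- c(if (kids[1] < 0) hc$labels[-kids[1]] else members[[kids[1]]],
             if (kids[2] < 0) hc$labels[-kids[2]] else members[[kids[2]]])
    members[[k]] <- ids
    keys[k] <- paste(sort(ids), collapse = "\r")
  }
  list(members = members, keys = keys)
}

#' Bootstrap support for dendrogram nodes
#'
#' Resamples the feature-matrix bins (columns) with replacement `n_boot`
#' times, recomputes the weighted-similarity dendrogram each time, and
#' reports for every internal node the fraction of replicates containing a
#' clade with exactly the same leaves (bootstrap probability, BP). With
#' `au = TRUE`, an approximately unbiased (AU) value is added via multiscale
#' bootstrap: ten resampling scales from 0.5 to 1.4 times the bin count and
#' a probit regression `z(r) = v * sqrt(r) + c / sqrt(r)`, giving
#' `AU = 1 - pnorm(v - c)`.
#'
#' @param fm a [feature_matrix()] with at least 3 spectra.
#' @param n_boot bootstrap replicates per scale (at least 100).
#' @param seed integer RNG seed.
#' @param combiner similarity combiner (see [weight_cosine()]).
#' @param linkage linkage method.
#' @param au also compute AU values by multiscale bootstrap.
#' @return data.frame of class `cluster_support`: one row per internal node
#'   with `node, n_leaves, bp` (and `au`); `attr(, "hclust")` is the
#'   baseline dendrogram, `attr(, "n_boot")` the replicate count.
#' @export
bootstrap_support <- function(fm, n_boot = 1000, seed = 1,
                              combiner = "multiply", linkage = "average",
                              au = FALSE) {
  if (nrow(fm$intensity) < 3)
    stop("bootstrap support needs >= 3 spectra", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  base_W <- similarity_bundle(fm, combiner = combiner)$weighted
  base_hc <- hclust(as.dist(1 - base_W), method = linkage)
  base <- clade_keys(base_hc)
  nb <- ncol(fm$intensity)
  set.seed(seed)
  scales <- if (au) seq(0.5, 1.4, length.out = 10) else 1
  hits <- matrix(0, length(base$keys), length(scales))
  for (si in seq_along(scales)) {
    m <- max(2L, round(scales[si] * nb))
    for (b in seq_len(n_boot)) {
      cols <- sample.int(nb, m, replace = TRUE)
      sub <- feature_matrix(seq_len(m),     # placeholder ascending centers
                            fm$spectrum_ids,
                            fm$intensity[, cols, drop = FALSE])
      W <- tryCatch(
        suppressWarnings(similarity_bundle(sub, combiner = combiner)$weighted),
        error = function(e) NULL)
      if (is.null(W)) next
      hc <- hclust(as.dist(1 - W), method = linkage)
      keys <- clade_keys(hc)$keys
      hits[, si] <- hits[, si] + (base$keys %in% keys)
    }
  }
  bpmat <- hits / n_boot
  out <- data.frame(node = seq_along(base$keys),
                    n_leaves = lengths(base$members),
                    bp = bpmat[, which.min(abs(scales - 1))])
  if (au) out$au <- vapply(seq_len(nrow(bpmat)), function(k)
    au_from_multiscale(bpmat[k, ], scales), 0)
  class(out) <- c("cluster_support", "data.frame")
  attr(out, "hclust") <- base_hc
  attr(out, "n_boot") <- n_boot
  out
}

# probit-regression AU from per-scale bootstrap proportions
au_from_multiscale <- function(bp, scales) {
  eps <- 1e-3
  bp <- pmin(pmax(bp, eps), 1 - eps)
  z <- qnorm(1 - bp)
  sr <- sqrt(scales)
  fit <- tryCatch(lm(z ~ 0 + sr + I(1 / sr)), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  v <- coef(fit)[["sr"]]; cc <- coef(fit)[["I(1/sr)"]]
  unname(1 - pnorm(v - cc))
}

#' Export a supported dendrogram as newick
#'
#' Internal nodes are labelled `bp` (or `au|bp`) as percentages; branch
#' lengths are the merge-height differences of the average-linkage tree.
#'
#' @param support a [bootstrap_support()] result.
#' @param path output file.
#' @return the newick string, invisibly.
#' @export
write_newick <- function(support, path = NULL) {
  hc <- attr(support, "hclust")
  lab <- if ("au" %in% names(support))
    sprintf("%.0f|%.0f", 100 * support$au, 100 * support$bp)
  else sprintf("%.0f", 100 * support$bp)
  node_str <- function(k, parent_h) {
    if (k < 0) return(sprintf("%s:%.6f", hc$labels[-k], parent_h))
    h <- hc$height[k]
    kids <- hc$merge[k, ]
    sprintf("(%s,%s)%s:%.6f", node_str(kids[1], h), node_str(kids[2], h),
            lab[k], parent_h - h)
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  kids <- hc$merge[root, ]
  nwk <- sprintf("(%s,%s)%s;", node_str(kids[1], h), node_str(kids[2], h),
                 lab[root])
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 =
#' identical partitions, ~0 = random agreement.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
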