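#' MTU abundance vector
#'
#' Per-MTU isolate counts plus the derived quantities driving Chao-type
#' estimators: total isolates `n`, observed richness `s_obs`, singletons
#' `f1` (MTUs with exactly one isolate) and doubletons `f2`.
#'
#' @param counts named (or unnamed) integer vector of isolates per MTU, all
#'   at least 1.
#' @return object of class `abundance_vector`.
#' @export
abundance_vector <- function(counts) {
  counts <- as.integer(counts)
  if (!length(counts) || any(counts < 1))
    stop("abundances must be positive integers", call. = FALSE)
  structure(list(counts = counts, n = sum(counts), s_obs = length(counts),
                 f1 = sum(counts == 1), f2 = sum(counts == 2)),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("<abundance_vector> n=%d isolates, s_obs=%d MTUs, f1=%d, f2=%d\n",
              x$n, x$s_obs, x$f1, x$f2))
  invisible(x)
}

#' Abundance vector from an MTU clustering
#'
#' @param mtus a [cluster_mtus()] result (or its `table` data.frame).
#' @return an [abundance_vector()].
#' @export
abundance_from_mtus <- function(mtus) {
  tab <- if (inherits(mtus, "mtu_result")) mtus$table else mtus
  abundance_vector(as.integer(table(tab$mtu_id)))
}

# Chao1 estimate of the number of undetected MTUs
chao_f0 <- function(av) {
  n <- av$n
  if (av$f2 > 0) ((n - 1) / n) * av$f1^2 / (2 * av$f2)
  else ((n - 1) / n) * av$f1 * (av$f1 - 1) / 2
}

#' Rarefaction and extrapolation of MTU richness
#'
#' Interpolation uses the exact hypergeometric rarefaction formula
#' `E[S(m)] = s_obs - sum_i C(n - x_i, m) / C(n, m)`; extrapolation to
#' `n + m*` uses the Chao1-based
#' `S(n + m*) = s_obs + f0_hat * (1 - (1 - f1 / (n * f0_hat + f1))^m*)`.
#' Sample coverage along the grid uses the abundance-based coverage
#' estimator. 95% confidence half-widths come from a seeded multinomial
#' bootstrap of the abundance vector.
#'
#' @param av an [abundance_vector()].
#' @param m_grid sample sizes (default: ~40 knots from 1 to `2n`).
#' @param n_boot bootstrap replicates for the CIs (default 200).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return data.frame of class `diversity_estimate`: `m, method, richness,
#'   coverage, ci_lo, ci_hi`; `attr(, "chao1")` is the asymptotic richness
#'   estimate `s_obs + f0_hat`.
#' @export
rarefy_extrapolate <- function(av, m_grid = NULL, n_boot = 200, seed = 1,
                               conf = 0.95) {
  n <- av$n
  if (n < 2) stop("need n >= 2 isolates", call. = FALSE)
  if (is.null(m_grid))
    m_grid <- unique(c(round(seq(1, 2 * n, length.out = 40)), n, 2 * n))
  m_grid <- sort(unique(as.integer(m_grid)))
  if (any(m_grid < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  point <- richness_curve(av$counts, m_grid)
  cover <- coverage_curve(av$counts, m_grid)
  # bootstrap: multinomial resamples of the observed relative abundances
  set.seed(seed)
  p <- av$counts / n
  boot_rich <- matrix(NA_real_, n_boot, length(m_grid))
  boot_cov <- matrix(NA_real_, n_boot, length(m_grid))
  for (b in seq_len(n_boot)) {
    x <- as.integer(rmultinom(1, n, p))
    x <- x[x > 0]
    boot_rich[b, ] <- richness_curve(x, m_grid)
    boot_cov[b, ] <- coverage_curve(x, m_grid)
  }
  z <- qnorm(1 - (1 - conf) / 2)
  hw_r <- z * apply(boot_rich, 2, sd)
  hw_c <- z * apply(boot_cov, 2, sd)
  out <- data.frame(m = m_grid,
                    method = ifelse(m_grid <= n, "interpolated", "extrapolated"),
                    richness = point, coverage = cover,
                    ci_lo = pmax(point - hw_r, 0), ci_hi = point + hw_r,
                    cov_lo = pmax(cover - hw_c, 0),
                    cov_hi = pmin(cover + hw_c, 1))
  class(out) <- c("diversity_estimate", "data.frame")
  attr(out, "chao1") <- av$s_obs + chao_f0(av)
  out
}

# expected richness at each m (interpolation for m <= n, Chao1 extrapolation
# beyond) for a raw count vector
richness_curve <- function(counts, m_grid) {
  av <- abundance_vector(counts)
  n <- av$n
  vapply(m_grid, function(m) {
    if (m <= n) {
      lnum <- lchoose(n - counts, m)  # -Inf where n - x_i < m
      av$s_obs - sum(exp(lnum - lchoose(n, m)))
    } else {
      f0 <- chao_f0(av)
      if (f0 == 0 || av$f1 == 0) av$s_obs
      else av$s_obs + f0 * (1 - (1 - av$f1 / (n * f0 + av$f1))^(m - n))
    }
  }, 0)
}

# abundance-based sample-coverage estimate along the size grid (iNEXT-style)
coverage_curve <- function(counts, m_grid) {
  av <- abundance_vector(counts)
  n <- av$n
  f1 <- av$f1; f2 <- av$f2
  chat_n <- coverage(av)
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else if (f1 > 0) 2 / ((n - 1) * (f1 - 1) + 2)
       else 1
  vapply(m_grid, function(m) {
    if (m < n) {
      # expected coverage of a subsample of size m
      lnum <- lchoose(n - counts, m)
      1 - sum(counts / n * exp(lnum - lchoose(n - 1, m)))
    } else if (m == n) chat_n
    else 1 - f1 / n * (1 - A)^(m - n + 1)
  }, 0)
}

#' Sample coverage of the library
#'
#' Abundance-based coverage estimator: the estimated fraction of the
#' community's individuals belonging to MTUs already represented in the
#' library, `C_hat = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`. With no
#' singletons the estimate is 1.
#'
#' @param av an [abundance_vector()].
#' @return scalar coverage in \[0, 1\].
#' @export
coverage <- function(av) {
  n <- av$n
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (av$f1 == 0) return(1)
  1 - (av$f1 / n) * ((n - 1) * av$f1 / ((n - 1) * av$f1 + 2 * av$f2))
}
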