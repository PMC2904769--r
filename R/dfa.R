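#' Default DFA box sizes
#'
#' Approximately log-uniformly spaced integer box sizes in
#' `[4, floor(N/4)]` (about 16 before deduplication). The lower bound 4 is
#' the smallest box in which a linear fit leaves two residual degrees of
#' freedom; the upper bound guarantees at least four boxes are averaged at
#' the largest scale. Signals `stridegem_too_short_series` if fewer than 6
#' distinct sizes are available.
#'
#' @param N Series length (`>= 16`).
#' @param n_sizes Target number of sizes before deduplication.
#' @return Strictly increasing integer vector of box sizes.
#' @export
default_box_sizes <- function(N, n_sizes = 16L) {
  if (!is.numeric(N) || N < 16)
    stop_stridegem("series too short for DFA (need N >= 16)",
                   "too_short_series")
  nmax <- floor(N / 4)
  sizes <- unique(round(exp(seq(log(4), log(nmax), length.out = n_sizes))))
  sizes <- sizes[sizes >= 4]
  if (length(sizes) < 6L)
    stop_stridegem(
      sprintf("only %d distinct box sizes available for N = %d (need >= 6)",
              length(sizes), N),
      "too_short_series")
  as.integer(sizes)
}

#' Detrended fluctuation analysis (DFA)
#'
#' First-order DFA of a time series, yielding the scaling exponent `alpha`
#' that summarizes stride-to-stride temporal structure: `alpha > 1/2`
#' indicates statistical persistence, `alpha < 1/2` anti-persistence,
#' `alpha = 1/2` uncorrelated noise, and `alpha ~ 1.5` Brownian motion
#' (integrated white noise).
#'
#' The series is integrated after mean removal,
#' `y(k) = sum_{i<=k} (x_i - mean(x))`; for each box size `n` the profile
#' is partitioned into `floor(N/n)` non-overlapping boxes from the start
#' (any tail remainder is discarded), a least-squares polynomial of order
#' `detrend_order` is removed in each box, and `F(n)` is the root mean
#' square of the residuals pooled over all boxes. `alpha` is the
#' least-squares slope of `log10 F(n)` versus `log10 n` over all box
#' sizes, each size entering once, unweighted.
#'
#' @param x Numeric series (not constant).
#' @param box_sizes Integer box sizes; default [default_box_sizes()] of
#'   `length(x)`. Every size must satisfy `floor(N/n) >= 2` and leave at
#'   least `detrend_order + 2` residual degrees of freedom.
#' @param detrend_order Polynomial detrending order (default 1, standard
#'   DFA-1).
#' @return An object of class `dfa_result`: list with `box_sizes`, `F`,
#'   `alpha`, `fit_intercept`, `r_squared`, `n_points_fit`,
#'   `detrend_order`, `N`.
#' @examples
#' set.seed(1)
#' dfa(rnorm(500))$alpha          # ~ 0.5 (uncorrelated)
#' dfa(cumsum(rnorm(500)))$alpha  # ~ 1.5 (Brownian motion)
#' @export
dfa <- function(x, box_sizes = NULL, detrend_order = 1L) {
  x <- as.numeric(x)
  N <- length(x)
  if (anyNA(x))
    stop_stridegem("missing values are not allowed", "invalid_series")
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(N)
  box_sizes <- as.integer(box_sizes)
  if (is.unsorted(box_sizes, strictly = TRUE))
    stop_stridegem("box_sizes must be strictly increasing",
                   "invalid_series")
  if (any(box_sizes < detrend_order + 3L))
    stop_stridegem(
      sprintf("smallest box must be >= %d for order-%d detrending",
              detrend_order + 3L, detrend_order),
      "invalid_series")
  if (floor(N / max(box_sizes)) < 2L)
    stop_stridegem("largest box size leaves fewer than 2 boxes",
                   "too_short_series")
  if (diff(range(x)) == 0)
    stop_stridegem("constant input has no fluctuations to analyse",
                   "constant_input")
  y <- cumsum(x - mean(x))
  F <- vapply(box_sizes, function(n) {
    k <- N %/% n
    Y <- matrix(y[seq_len(n * k)], nrow = n)
    X <- outer(seq_len(n), 0:detrend_order, `^`)
    res <- stats::lm.fit(X, Y)$residuals
    sqrt(mean(res^2))
  }, numeric(1))
  if (any(F <= 0))
    stop_stridegem("zero fluctuation in some box (degenerate input)",
                   "constant_input")
  fit <- stats::lm(log10(F) ~ log10(box_sizes))
  structure(
    list(box_sizes = box_sizes, F = F,
         alpha = unname(stats::coef(fit)[2]),
         fit_intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n_points_fit = length(box_sizes),
         detrend_order = as.integer(detrend_order), N = N),
    class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "<dfa_result> alpha = %.4f (order-%d detrend, %d box sizes %d..%d, N = %d, R^2 = %.4f)\n",
    x$alpha, x$detrend_order, x$n_points_fit,
    min(x$box_sizes), max(x$box_sizes), x$N, x$r_squared))
  invisible(x)
}

#' @export
plot.dfa_result <- function(x, ...) {
  graphics::plot(log10(x$box_sizes), log10(x$F),
                 xlab = "log10 box size n", ylab = "log10 F(n)",
                 main = sprintf("DFA: alpha = %.3f", x$alpha), ...)
  graphics::abline(x$fit_intercept, x$alpha, lty = 2)
  invisible(x)
}
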