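#' Fractional Gaussian noise by spectral synthesis
#'
#' Generates a zero-mean, unit-variance Gaussian series whose DFA scaling
#' exponent is approximately `H`. For `H <= 1`, white Gaussian Fourier
#' coefficients are shaped by `f^{-(2H-1)/2}` (so the power spectrum
#' follows `f^{-(2H-1)}`), conjugate symmetry is enforced and the inverse
#' transform standardized. For `1 < H <= 1.5` the series is the cumulative
#' sum of an `H - 1` noise (e.g. `H = 1.5` is integrated white noise,
#' i.e. Brownian motion). This generator is the independent oracle used to
#' calibrate the DFA implementation.
#'
#' @param H Target scaling exponent, `0 < H <= 1.5`.
#' @param N Series length, `>= 32`.
#' @param seed Optional integer seed.
#' @return Numeric series of length `N` with mean 0 and SD 1.
#' @examples
#' dfa(generate_fgn(0.8, 500, seed = 1))$alpha  # ~ 0.8
#' @export
generate_fgn <- function(H, N, seed = NULL) {
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H <= 0 || H > 1.5)
    stop_stridegem("H must be in (0, 1.5]", "invalid_H")
  if (!is.numeric(N) || N < 32)
    stop_stridegem("N must be >= 32", "invalid_series")
  N <- as.integer(N)
  with_seed(seed, {
    if (H > 1) {
      x <- cumsum(fgn_spectral(H - 1, N))
    } else {
      x <- fgn_spectral(H, N)
    }
    (x - mean(x)) / stats::sd(x)
  })
}

# Spectral synthesis core for 0 < H <= 1: shape complex white noise by
# f^{-(2H-1)/2} on the half spectrum, mirror, invert.
fgn_spectral <- function(H, N) {
  half <- n_free_phase_bins(N)
  f <- (1:half) / N
  amp <- f^(-(2 * H - 1) / 2)
  z <- rep(0 + 0i, N)
  coef <- amp * complex(real = stats::rnorm(half),
                        imaginary = stats::rnorm(half)) / sqrt(2)
  z[2:(half + 1)] <- coef
  z[N:(N - half + 1)] <- Conj(coef)
  if (N %% 2L == 0L) {
    fN <- (N / 2) / N
    z[N / 2 + 1] <- fN^(-(2 * H - 1) / 2) * stats::rnorm(1)
  }
  Re(stats::fft(z, inverse = TRUE)) / N
}

#' Simulate a human-like treadmill trial
#'
#' Runs the over-correcting (OVC) controller preset -- the model variant
#' whose output reproduces the statistical signature of human treadmill
#' walking: persistent stride times and lengths (`alpha > 1/2`),
#' anti-persistent stride speeds (`alpha < 1/2`), mean stride time near
#' 1.105 s and mean stride length near 1.337 m at belt speed 1.21 m/s.
#' The returned trial is guaranteed to satisfy the belt constraint
#' (belt-violating draws are regenerated from derived sub-seeds).
#'
#' @param n_strides Number of strides, in `[200, 1000]` (default 272, a
#'   typical trial length).
#' @param seed Optional integer seed.
#' @param d_max Half belt length (default 0.864).
#' @return A [stride_series()] with condition `"humanlike"`.
#' @export
make_humanlike_trial <- function(n_strides = 272L, seed = NULL,
                                 d_max = 0.864) {
  if (n_strides < 200L || n_strides > 1000L)
    stop_stridegem("n_strides must be in [200, 1000]", "invalid_series")
  cfg <- controller_config("OVC", n_strides = n_strides, seed = seed)
  for (att in 0:99) {
    cand_cfg <- cfg
    if (!is.null(seed) && att > 0L)
      cand_cfg$seed <- derive_seed(seed, 0L, att)
    s <- simulate_walker(cand_cfg, rep_index = 1L, d_max = d_max)
    if (attr(s, "belt_check")$ok) {
      s$condition <- "humanlike"
      return(s)
    }
  }
  stop_stridegem("no belt-respecting trial within 100 attempts",
                 "constraint_unsatisfiable")
}

#' Adversarial and degenerate fixture trials
#'
#' A named collection of small trials that exercise documented error and
#' edge-case branches: a constant-stride-time trial (degenerate SD for
#' GEM normalization), a 2-stride trial (too short for DFA), a trial that
#' walks off the belt, a trial exactly on the GEM (`L_i = v T_i`, zero
#' perpendicular variance), and a trial where the mean of per-stride
#' speeds differs from total distance over total time.
#'
#' @param v Belt speed used for the fixtures (default 1.21).
#' @return Named list of [stride_series()].
#' @export
make_adversarial_trials <- function(v = 1.21) {
  n <- 64L
  tt <- seq(1.0, 1.2, length.out = n)
  list(
    constant_T = stride_series(T = rep(1.1, n),
                               L = 1.33 + 0.01 * sin(seq_len(n)), v = v,
                               trial_id = "constant_T",
                               condition = "adversarial"),
    two_stride = stride_series(T = c(1.0, 1.2), L = c(1.3, 1.4), v = v,
                               trial_id = "two_stride",
                               condition = "adversarial"),
    belt_violating = stride_series(T = rep(1.0, n), L = rep(1.0, n) + v,
                                   v = v, trial_id = "belt_violating",
                                   condition = "adversarial"),
    on_gem = stride_series(T = tt, L = v * tt, v = v, trial_id = "on_gem",
                           condition = "adversarial"),
    speed_mean_mismatch = stride_series(T = c(1, 2), L = c(1, 1), v = v,
                                        trial_id = "speed_mean_mismatch",
                                        condition = "adversarial"))
}
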