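#' Surrogate generation settings
#'
#' Bundles the settings for constraint-respecting surrogate generation:
#' the surrogate family, how many surrogates per trial (20, matching the
#' convention of averaging each dependent measure over 20 surrogates), the
#' half belt length used for the walk-off check, the rejection-sampling
#' attempt cap, and the seed.
#'
#' @param kind `"shuffle"`, `"phase_randomized"` or `"paired_shuffle"`.
#' @param n_surrogates Number of surrogates to generate (default 20).
#' @param d_max Half belt length in meters (default 0.864).
#' @param max_attempts_per_surrogate Rejection-sampling cap (default 1000).
#' @param seed Optional integer seed.
#' @param share_phases For `phase_randomized` only: reuse one random phase
#'   vector for both T and L (default `FALSE`; phases are drawn separately
#'   for each series).
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(kind = c("shuffle", "phase_randomized",
                                      "paired_shuffle"),
                             n_surrogates = 20L, d_max = 0.864,
                             max_attempts_per_surrogate = 1000L,
                             seed = NULL, share_phases = FALSE) {
  kind <- match.arg(kind)
  if (n_surrogates < 1L)
    stop_stridegem("n_surrogates must be >= 1", "invalid_series")
  if (max_attempts_per_surrogate < 1L)
    stop_stridegem("max_attempts_per_surrogate must be >= 1",
                   "invalid_series")
  if (d_max <= 0)
    stop_stridegem("d_max must be > 0", "invalid_series")
  structure(list(kind = kind, n_surrogates = as.integer(n_surrogates),
                 d_max = d_max,
                 max_attempts_per_surrogate =
                   as.integer(max_attempts_per_surrogate),
                 seed = seed, share_phases = isTRUE(share_phases)),
            class = "surrogate_config")
}

#' Independently shuffled surrogate
#'
#' Shuffles the stride-time and stride-length series independently of one
#' another, in random order. The surrogate keeps the exact mean, variance
#' and value multiset of each series but destroys all temporal structure
#' and any coupling between T and L. It represents a walker choosing each
#' stride's time and length independently of the GEM, of each other, and
#' of previous strides. Uses the current RNG stream; seed via `set.seed()`
#' or [generate_valid_surrogates()].
#'
#' @param series A [stride_series()].
#' @return A [stride_series()] with condition `"surrogate/shuffle"`.
#' @export
shuffle_surrogate <- function(series) {
  validate_stride_series(series)
  n <- length(series$T)
  if (n < 2L) return(series)
  stride_series(T = series$T[sample.int(n)], L = series$L[sample.int(n)],
                v = series$v, trial_id = series$trial_id,
                condition = "surrogate/shuffle")
}

#' Paired shuffled surrogate
#'
#' Applies one random permutation jointly to the stride-time and
#' stride-length series, preserving the multiset of `(T_i, L_i)` pairs
#' exactly -- hence the stride cloud, every stride speed, and the
#' tangent/perpendicular variance ratio of the GEM decomposition -- while
#' destroying temporal order. It represents strides that may be coupled
#' mechanically but are chosen independently of the GEM and of previous
#' strides.
#'
#' @param series A [stride_series()].
#' @return A [stride_series()] with condition `"surrogate/paired_shuffle"`.
#' @export
paired_shuffle_surrogate <- function(series) {
  validate_stride_series(series)
  n <- length(series$T)
  if (n < 2L) return(series)
  idx <- sample.int(n)
  stride_series(T = series$T[idx], L = series$L[idx], v = series$v,
                trial_id = series$trial_id,
                condition = "surrogate/paired_shuffle")
}

#' Phase-randomized surrogate of a numeric sequence
#'
#' Classic phase randomization: the discrete Fourier transform of the
#' mean-removed series has the phases of all non-DC, non-Nyquist bins
#' replaced by iid uniform phases (conjugate symmetry enforced; for even
#' lengths the Nyquist bin keeps its real value), amplitudes untouched,
#' and the mean restored after the inverse transform. The surrogate's
#' periodogram -- hence all linear autocorrelation -- equals the
#' original's; amplitude distribution and any nonlinear structure are
#' randomized. It represents fluctuations that stay temporally correlated
#' across strides but ignore the GEM.
#'
#' @param x Numeric series, length `>= 8`.
#' @return Numeric series of the same length and mean.
#' @export
phase_randomized_surrogate <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 8L)
    stop_stridegem("phase randomization needs N >= 8", "invalid_series")
  phase_randomize_with(x, stats::runif(n_free_phase_bins(N), 0, 2 * pi))
}

# Number of DFT bins whose phase is free to randomize (non-DC, non-Nyquist).
n_free_phase_bins <- function(N) {
  if (N %% 2L == 0L) N / 2L - 1L else (N - 1L) / 2L
}

# Apply a given phase vector (length n_free_phase_bins(N)) to a series.
phase_randomize_with <- function(x, phases) {
  x <- as.numeric(x)
  N <- length(x)
  mu <- mean(x)
  z <- stats::fft(x - mu)
  half <- n_free_phase_bins(N)
  if (half >= 1L) {
    k <- seq(2L, half + 1L)
    z[k] <- Mod(z[k]) * exp(1i * phases)
    z[N + 2L - k] <- Conj(z[k])
  }
  # DC (k=1) untouched; even-N Nyquist bin (k = N/2 + 1) keeps its value
  Re(stats::fft(z, inverse = TRUE)) / N + mu
}

# Build one surrogate candidate of the configured kind.
make_surrogate_candidate <- function(series, cfg) {
  switch(cfg$kind,
    shuffle = shuffle_surrogate(series),
    paired_shuffle = paired_shuffle_surrogate(series),
    phase_randomized = {
      if (cfg$share_phases) {
        phases <- stats::runif(n_free_phase_bins(length(series$T)), 0, 2 * pi)
        Ts <- phase_randomize_with(series$T, phases)
        Ls <- phase_randomize_with(series$L, phases)
      } else {
        Ts <- phase_randomized_surrogate(series$T)
        Ls <- phase_randomized_surrogate(series$L)
      }
      if (any(Ts <= 0) || any(Ls <= 0)) return(NULL)  # leaves positive orthant
      stride_series(T = Ts, L = Ls, v = series$v,
                    trial_id = series$trial_id,
                    condition = "surrogate/phase_randomized")
    })
}

#' Generate belt-constraint-respecting surrogates
#'
#' Draws surrogates of the configured kind, rejecting any candidate whose
#' net cumulative displacement would carry the walker off the treadmill
#' (`|d_net| > d_max` at any stride) or -- relevant for phase-randomized
#' surrogates, which can leave the positive orthant -- any candidate with
#' a nonpositive stride time or length. Every returned surrogate is a
#' hypothetical trial that would have completed without walking off the
#' belt. Rejection counts are reported.
#'
#' @param series A [stride_series()] that itself satisfies the belt
#'   constraint.
#' @param cfg A [surrogate_config()].
#' @return An object of class `surrogate_set`: list with `surrogates` (a
#'   list of [stride_series()]) and `report` (kind, attempts per
#'   surrogate, rejection counts by reason).
#' @export
generate_valid_surrogates <- function(series, cfg = surrogate_config()) {
  validate_stride_series(series)
  if (!inherits(cfg, "surrogate_config"))
    stop_stridegem("cfg must be a surrogate_config", "invalid_series")
  if (!check_belt_constraint(series, cfg$d_max)$ok)
    stop_stridegem(
      "original series violates the belt constraint; surrogates undefined",
      "invalid_series")
  with_seed(cfg$seed, {
    surrogates <- vector("list", cfg$n_surrogates)
    attempts <- integer(cfg$n_surrogates)
    rejected_belt <- 0L
    rejected_positivity <- 0L
    for (i in seq_len(cfg$n_surrogates)) {
      ok <- FALSE
      for (att in seq_len(cfg$max_attempts_per_surrogate)) {
        cand <- make_surrogate_candidate(series, cfg)
        if (is.null(cand)) { rejected_positivity <- rejected_positivity + 1L; next }
        if (!check_belt_constraint(cand, cfg$d_max)$ok) {
          rejected_belt <- rejected_belt + 1L; next
        }
        surrogates[[i]] <- cand
        attempts[i] <- att
        ok <- TRUE
        break
      }
      if (!ok)
        stop_stridegem(
          sprintf("no valid %s surrogate within %d attempts (surrogate %d)",
                  cfg$kind, cfg$max_attempts_per_surrogate, i),
          "constraint_unsatisfiable")
    }
    structure(
      list(surrogates = surrogates,
           report = list(kind = cfg$kind,
                         n_surrogates = cfg$n_surrogates,
                         d_max = cfg$d_max,
                         attempts = attempts,
                         total_attempts = sum(attempts) +
                           rejected_positivity,
                         rejected_belt = rejected_belt,
                         rejected_positivity = rejected_positivity)),
      class = "surrogate_set")
  })
}

#' @export
print.surrogate_set <- function(x, ...) {
  r <- x$report
  cat(sprintf("<surrogate_set> %d %s surrogates (d_max = %g m)\n",
              r$n_surrogates, r$kind, r$d_max))
  cat(sprintf("  rejections: %d belt, %d positivity\n",
              r$rejected_belt, r$rejected_positivity))
  invisible(x)
}
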