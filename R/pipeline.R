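#' Per-trial summary statistics
#'
#' Mean, standard deviation and DFA scaling exponent for each primary
#' stride variable of a trial: stride time `T`, stride length `L`, stride
#' speed `S = L/T`, net cumulative displacement `d_net`, and -- when a GEM
#' frame is supplied (or `gem = TRUE`) -- the tangent and perpendicular
#' deviations `delta_T`, `delta_P`. Returned tidy, one row per variable.
#' Variables whose DFA is degenerate (constant series, e.g. `delta_P` of a
#' noiseless on-GEM trial) get `alpha = NA` and a note.
#'
#' @param series A [stride_series()].
#' @param gem `TRUE` to fit a per-trial frame with defaults, `FALSE` for
#'   basic variables only, or a [fit_gem_frame()] object to reuse.
#' @param box_sizes Optional DFA box sizes passed to [dfa()].
#' @param d_max Half belt length recorded in the attributes (default
#'   0.864).
#' @return A data.frame of class `trial_summary` with columns `trial_id`,
#'   `condition`, `variable`, `mean`, `sd`, `alpha`, `n`, and attributes
#'   `max_d` / `min_d` (belt excursions).
#' @export
summarize_trial <- function(series, gem = TRUE, box_sizes = NULL,
                            d_max = 0.864) {
  validate_stride_series(series)
  S <- stride_speeds(series)
  d <- dnet(series)
  vars <- list(T = series$T, L = series$L, S = S, d_net = d)
  if (inherits(gem, "gem_frame")) {
    dev <- gem_decompose(series, gem)
    vars$delta_T <- dev$delta_T
    vars$delta_P <- dev$delta_P
  } else if (isTRUE(gem)) {
    dev <- gem_decompose(series, fit_gem_frame(series))
    vars$delta_T <- dev$delta_T
    vars$delta_P <- dev$delta_P
  }
  safe_alpha <- function(x) {
    # numerically constant series (e.g. delta_P of a noiseless on-GEM
    # trial) have no fluctuations to scale; flag rather than fit noise
    if (stats::sd(x) <= 1e-12 * (abs(mean(x)) + 1)) return(NA_real_)
    tryCatch(dfa(x, box_sizes = box_sizes)$alpha,
             stridegem_constant_input = function(e) NA_real_)
  }
  out <- data.frame(
    trial_id = series$trial_id, condition = series$condition,
    variable = names(vars),
    mean = vapply(vars, mean, numeric(1)),
    sd = vapply(vars, stats::sd, numeric(1)),
    alpha = vapply(vars, safe_alpha, numeric(1)),
    n = length(series$T), row.names = NULL)
  attr(out, "max_d") <- max(d)
  attr(out, "min_d") <- min(d)
  attr(out, "belt_ok") <- check_belt_constraint(series, d_max)$ok
  class(out) <- c("trial_summary", "data.frame")
  out
}

#' Full single-trial analysis
#'
#' The complete per-trial pipeline applied to one stride series: fit a
#' GEM frame, decompose into `delta_T` / `delta_P`, run DFA on every
#' primary variable, and check the belt constraint. This is the analysis
#' applied identically to experimental-style data, surrogates, and model
#' simulations.
#'
#' @param series A [stride_series()].
#' @param normalization,operating_point Passed to [fit_gem_frame()].
#' @param box_sizes Optional DFA box sizes.
#' @param d_max Half belt length (default 0.864).
#' @return An object of class `trial_analysis`: list with `summary` (a
#'   [summarize_trial()] data.frame), `frame`, `deviations`, `belt`.
#' @export
analyze_trial <- function(series,
                          normalization = c("per-series-SD", "none"),
                          operating_point = c("sample-mean",
                                              "projected-to-GEM"),
                          box_sizes = NULL, d_max = 0.864) {
  validate_stride_series(series)
  frame <- fit_gem_frame(series, normalization = match.arg(normalization),
                         operating_point = match.arg(operating_point))
  structure(
    list(summary = summarize_trial(series, gem = frame,
                                   box_sizes = box_sizes, d_max = d_max),
         frame = frame,
         deviations = gem_decompose(series, frame),
         belt = check_belt_constraint(series, d_max)),
    class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("<trial_analysis>\n")
  print(x$summary)
  cat(sprintf("  belt: ok = %s, d_net in [%.3f, %.3f] m\n",
              x$belt$ok, x$belt$min_d, x$belt$max_d))
  invisible(x)
}

#' Compare a trial against its surrogates
#'
#' For each requested surrogate family, generates `n_surrogates`
#' belt-respecting surrogates, applies the identical per-trial analysis
#' (per-surrogate GEM frame, DFA), and averages each dependent measure
#' across the surrogates. The original trial's values are reported
#' alongside, one row per variable per source.
#'
#' @param series A [stride_series()].
#' @param kinds Character vector of surrogate kinds (default all three).
#' @param n_surrogates Surrogates per kind (default 20).
#' @param d_max Half belt length (default 0.864).
#' @param seed Optional integer seed (sub-seeds derived per kind).
#' @param box_sizes Optional DFA box sizes.
#' @return A data.frame with columns `source` (`"original"` or the kind),
#'   `variable`, `mean`, `sd`, `alpha`, plus attribute `"reports"` (the
#'   per-kind generation reports).
#' @export
compare_surrogates <- function(series,
                               kinds = c("shuffle", "phase_randomized",
                                         "paired_shuffle"),
                               n_surrogates = 20L, d_max = 0.864,
                               seed = NULL, box_sizes = NULL) {
  validate_stride_series(series)
  kinds <- match.arg(kinds, several.ok = TRUE)
  keep <- c("T", "L", "S", "delta_T", "delta_P")
  orig <- summarize_trial(series, box_sizes = box_sizes, d_max = d_max)
  orig <- orig[orig$variable %in% keep,
               c("variable", "mean", "sd", "alpha")]
  out <- cbind(source = "original", orig)
  reports <- list()
  for (ki in seq_along(kinds)) {
    kind <- kinds[ki]
    cfg <- surrogate_config(kind = kind, n_surrogates = n_surrogates,
                            d_max = d_max,
                            seed = if (is.null(seed)) NULL
                                   else derive_seed(seed, ki))
    set <- generate_valid_surrogates(series, cfg)
    reports[[kind]] <- set$report
    sums <- lapply(set$surrogates, function(s) {
      sm <- summarize_trial(s, box_sizes = box_sizes, d_max = d_max)
      sm[sm$variable %in% keep, c("variable", "mean", "sd", "alpha")]
    })
    avg <- sums[[1]]
    for (col in c("mean", "sd", "alpha"))
      avg[[col]] <- rowMeans(vapply(sums, function(x) x[[col]],
                                    numeric(nrow(avg))))
    out <- rbind(out, cbind(source = kind, avg))
  }
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Two-group one-way ANOVA for the direction comparison
#'
#' Compares a dependent measure between the tangent (`delta_T`) and
#' perpendicular (`delta_P`) directions across replicates with a standard
#' one-way two-group F test (equivalently a squared two-sample pooled t),
#' `df = (1, 2n - 2)`. Groups with (jointly) zero variance are flagged
#' rather than producing a spurious F.
#'
#' @param values_deltaT,values_deltaP Equal-length numeric vectors of the
#'   per-replicate measure in each direction, `n >= 2`.
#' @return List with `F`, `df` (length 2), `p`, and `degenerate` (TRUE if
#'   the within-group variance is zero).
#' @export
direction_anova <- function(values_deltaT, values_deltaP) {
  n <- length(values_deltaT)
  if (length(values_deltaP) != n)
    stop_stridegem("groups must have equal length", "invalid_series")
  if (n < 2L)
    stop_stridegem("need at least 2 observations per group",
                   "invalid_series")
  vals <- c(values_deltaT, values_deltaP)
  grp <- factor(rep(c("delta_T", "delta_P"), each = n))
  tab <- suppressWarnings(stats::anova(stats::aov(vals ~ grp)))
  ms_within <- tab["Residuals", "Mean Sq"]
  if (ms_within <= 0 || !is.finite(ms_within)) {
    return(list(F = if (tab["grp", "Sum Sq"] == 0) 0 else NA_real_,
                df = c(1L, 2L * n - 2L), p = NA_real_, degenerate = TRUE))
  }
  list(F = tab["grp", "F value"], df = c(1L, 2L * n - 2L),
       p = tab["grp", "Pr(>F)"], degenerate = FALSE)
}

#' Three-model contrast table
#'
#' Runs the MIP, POP and OVC presets under identical settings and
#' tabulates the aggregate statistics that distinguish them: the mean DFA
#' exponents of the tangent and perpendicular deviations, the
#' tangent/perpendicular SD ratio, and the direction F statistics. The
#' expected pattern: `alpha(delta_T)` near 1.5 for MIP and above the POP
#' and OVC values; `alpha(delta_P)` near 0.5 for MIP and POP and below
#' 0.5 (anti-persistent) only for OVC.
#'
#' @param seed Integer seed.
#' @param n_strides,n_reps Passed to [controller_config()].
#' @return A data.frame, one row per variant, plus attribute
#'   `"experiments"` holding the three [run_model_experiment()] objects.
#' @export
model_contrast_table <- function(seed = 1L, n_strides = 500L,
                                 n_reps = 20L) {
  variants <- c("MIP", "POP", "OVC")
  exps <- lapply(variants, function(vv)
    run_model_experiment(controller_config(vv, n_strides = n_strides,
                                           n_reps = n_reps, seed = seed)))
  names(exps) <- variants
  pull <- function(e, m) e$aggregate$mean[e$aggregate$measure == m]
  out <- data.frame(
    variant = variants,
    alpha_delta_T = vapply(exps, pull, numeric(1), m = "alpha_delta_T"),
    alpha_delta_P = vapply(exps, pull, numeric(1), m = "alpha_delta_P"),
    sd_ratio = vapply(exps, function(e)
      pull(e, "sd_delta_T") / pull(e, "sd_delta_P"), numeric(1)),
    F_sd = vapply(exps, function(e) e$anova_sd$F, numeric(1)),
    F_alpha = vapply(exps, function(e) e$anova_alpha$F, numeric(1)),
    row.names = NULL)
  attr(out, "experiments") <- exps
  out
}

#' Plot a stride series as a cloud around its GEM
#'
#' Scatter of normalized stride coordinates with the GEM line and the
#' operating point, the standard visual for GEM-structured variability.
#'
#' @param x A [stride_series()].
#' @param frame Optional [fit_gem_frame()]; fitted with defaults if
#'   missing.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stride_series <- function(x, frame = NULL, ...) {
  if (is.null(frame)) frame <- fit_gem_frame(x)
  Tn <- x$T / frame$sigma_T
  Ln <- x$L / frame$sigma_L
  graphics::plot(Tn, Ln, xlab = "T / sigma_T", ylab = "L / sigma_L",
                 main = sprintf("%s (%s)", x$trial_id, x$condition), ...)
  graphics::abline(0, frame$m_hat, lty = 2)
  graphics::points(frame$Tstar / frame$sigma_T,
                   frame$Lstar / frame$sigma_L, pch = 3, cex = 1.5)
  invisible(x)
}

#' @export
plot.gem_deviations <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$delta_T, type = "l", xlab = "stride",
                 ylab = expression(delta[T]), ...)
  graphics::plot(x$delta_P, type = "l", xlab = "stride",
                 ylab = expression(delta[P]), ...)
  invisible(x)
}
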