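#' Stochastic single-step controller configuration
#'
#' Configures the discrete stride-to-stride map
#' `x_{n+1} = x_n + G (I + N) u_n + eta_n`, where `x_n = (T_n, L_n)` is
#' the state at stride `n`, `u_n` the control input, `G = diag(g1, g2)`
#' additional plant gains, `N = diag(nu1, nu2)` multiplicative (motor
#' output) noise and `eta` additive (sensory/perceptual) noise, all noise
#' terms iid zero-mean Gaussian with standard deviations
#' `sigma_mult = (sigma1, sigma2)` and `sigma_add = (sigma3, sigma4)`.
#'
#' The controller minimizes the expected single-step cost
#' `C = w_e e^2 + w_p p^2 + w_u1 u1^2 + w_u2 u2^2`, where
#' `e = L_{n+1} - v T_{n+1}` is the goal-level error of the constant-speed
#' strategy (zero on the GEM) and `p = ||x_{n+1} - (Tstar, Lstar)||` the
#' distance from the preferred operating point. Three presets reproduce
#' the model family:
#'
#' * `"MIP"` -- strict minimum intervention: `w_p = 0`,
#'   `w_e = w_u1 = w_u2 = 10`, unit gains. Only goal-relevant deviations
#'   are corrected; the controller is neutrally stable along the GEM, so
#'   tangent deviations diffuse like Brownian motion.
#' * `"POP"` -- adds a weak pull (`w_p = 2.79`) toward the preferred
#'   operating point `Tstar = 1.105 s`, `Lstar = v Tstar` on the GEM.
#' * `"OVC"` -- the POP controller with plant gains raised to
#'   `g1 = g2 = 1.24`, so every goal-relevant correction slightly
#'   overshoots; perpendicular deviations become anti-persistent, the
#'   signature seen in human walking.
#'
#' All presets use `v = 1.21 m/s` and noise amplitudes
#' `sigma1 = sigma3 = 0.017`, `sigma2 = sigma4 = 0.010`.
#'
#' @param variant `"MIP"`, `"POP"` or `"OVC"`.
#' @param v Belt speed (m/s).
#' @param Tstar,Lstar Preferred operating point (s, m); `Lstar` defaults
#'   to `v * Tstar` (on the GEM).
#' @param w_e,w_p,w_u Cost weights: goal error, operating-point distance,
#'   and the two effort penalties (`w_u` is length 2). Presets supply the
#'   defaults; pass values to override.
#' @param gains Length-2 plant gains `(g1, g2)`.
#' @param sigma_mult,sigma_add Length-2 noise SDs.
#' @param n_strides Strides per simulated trial (default 500).
#' @param n_reps Replicate trials per experiment (default 20).
#' @param seed Optional integer seed; per-rep streams are derived from
#'   `(seed, rep_index)` so reps are independently reproducible.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(variant = c("MIP", "POP", "OVC"),
                              v = 1.21, Tstar = 1.105, Lstar = v * Tstar,
                              w_e = 10, w_p = NULL, w_u = c(10, 10),
                              gains = NULL,
                              sigma_mult = c(0.017, 0.010),
                              sigma_add = c(0.017, 0.010),
                              n_strides = 500L, n_reps = 20L,
                              seed = NULL) {
  variant <- match.arg(variant)
  if (is.null(w_p)) w_p <- if (variant == "MIP") 0 else 2.79
  if (is.null(gains)) gains <- if (variant == "OVC") c(1.24, 1.24) else c(1, 1)
  stopifnot(length(w_u) == 2L, length(gains) == 2L,
            length(sigma_mult) == 2L, length(sigma_add) == 2L)
  if (w_e <= 0)
    stop_stridegem("goal-error weight w_e must be > 0", "invalid_config")
  if (w_p < 0 || any(w_u < 0))
    stop_stridegem("cost weights must be nonnegative", "invalid_config")
  if (w_p == 0 && sum(w_u) == 0)
    stop_stridegem("cost is not coercive in u: need w_p > 0 or w_u > 0",
                   "invalid_config")
  if (any(sigma_mult < 0) || any(sigma_add < 0))
    stop_stridegem("noise SDs must be nonnegative", "invalid_config")
  if (v <= 0 || Tstar <= 0 || Lstar <= 0)
    stop_stridegem("v, Tstar, Lstar must be > 0", "invalid_config")
  if (n_strides < 1L || n_reps < 1L)
    stop_stridegem("n_strides and n_reps must be >= 1", "invalid_config")
  structure(
    list(variant = variant, v = v, Tstar = Tstar, Lstar = Lstar,
         w_e = w_e, w_p = w_p, w_u = w_u, gains = gains,
         sigma_mult = sigma_mult, sigma_add = sigma_add,
         n_strides = as.integer(n_strides), n_reps = as.integer(n_reps),
         seed = seed),
    class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf("<controller_config> %s: v = %g m/s, (T*, L*) = (%g, %g)\n",
              x$variant, x$v, x$Tstar, x$Lstar))
  cat(sprintf("  weights w_e = %g, w_p = %g, w_u = (%g, %g); gains = (%g, %g)\n",
              x$w_e, x$w_p, x$w_u[1], x$w_u[2], x$gains[1], x$gains[2]))
  cat(sprintf("  sigma_mult = (%g, %g), sigma_add = (%g, %g); %d strides x %d reps\n",
              x$sigma_mult[1], x$sigma_mult[2], x$sigma_add[1],
          x$sigma_add[2], x$n_strides, x$n_reps))
  invisible(x)
}

#' Optimal control input for the current stride
#'
#' Solves the controller's single-step stochastic optimization at state
#' `x_n = (T_n, L_n)`. The controller plans with its *internal* model of
#' the plant, `x_{n+1} = x_n + (I + N) u + eta` (unit gains: it does not
#' know about `G`), and chooses `u` to minimize the expected cost
#' `E[C]` subject to the equality constraint that the expected goal error
#' vanish, `E[e_{n+1}] = a . (x_n + u) = 0` with `a = (-v, 1)`. Because
#' the multiplicative noise is signal-dependent, the expected cost retains
#' curvature in `u` even under the constraint, and the minimizer is the
#' solution of
#' `Q u = -(w_p p0 + lambda/2 a)`,
#' `Q = diag(w_e a_i^2 s_i^2 + w_p s_i^2 + w_p + w_u_i)`,
#' with `s = sigma_mult`, `p0 = x_n - (Tstar, Lstar)`, and the Lagrange
#' multiplier fixed by `a . u = -e0`, `e0 = a . x_n`.
#'
#' On the GEM (`e0 = 0`) with `w_p = 0` the optimum is `u = 0`: the strict
#' minimum-intervention controller exerts no effort anywhere along the
#' manifold. Actual plant gains `G != I` (the OVC variant) make the
#' *applied* correction overshoot the planned one; the controller itself
#' is unchanged.
#'
#' @param x_n Numeric length-2 state `(T_n, L_n)`.
#' @param cfg A [controller_config()].
#' @return Numeric length-2 control input `(u1, u2)`.
#' @export
optimal_control_input <- function(x_n, cfg) {
  stopifnot(inherits(cfg, "controller_config"), length(x_n) == 2L)
  a <- c(-cfg$v, 1)
  s2 <- cfg$sigma_mult^2
  q <- cfg$w_e * a^2 * s2 + cfg$w_p * s2 + cfg$w_p + cfg$w_u
  if (any(q <= 0))
    stop_stridegem("singular control system (no curvature in u)",
                   "singular_system")
  e0 <- sum(a * x_n)
  p0 <- x_n - c(cfg$Tstar, cfg$Lstar)
  z1 <- cfg$w_p * p0 / q      # Q^{-1} (w_p p0)
  z2 <- a / q                 # Q^{-1} a
  lam2 <- (e0 - sum(a * z1)) / sum(a * z2)  # lambda / 2
  -(z1 + lam2 * z2)
}

#' One step of the stride map
#'
#' Advances the true plant one stride:
#' `x_{n+1} = x_n + G (I + diag(nu)) u + eta`, with `nu = sigma_mult *
#' noise_draws[1:2]` and `eta = sigma_add * noise_draws[3:4]`. With zero
#' input and zero noise successive strides simply repeat (`x_{n+1} =
#' x_n`), reflecting the limit-cycle nature of steady walking.
#'
#' @param x_n Numeric length-2 state `(T_n, L_n)`.
#' @param u Numeric length-2 control input.
#' @param noise_draws Numeric length-4 standard-normal draws
#'   `(nu1, nu2, eta1, eta2)` before scaling; pass `rep(0, 4)` for a
#'   noiseless step.
#' @param cfg A [controller_config()].
#' @return Numeric length-2 next state. Signals
#'   `stridegem_nonpositive_state` if a component becomes `<= 0`.
#' @export
stride_map_step <- function(x_n, u, noise_draws, cfg) {
  stopifnot(length(x_n) == 2L, length(u) == 2L, length(noise_draws) == 4L)
  nu <- cfg$sigma_mult * noise_draws[1:2]
  eta <- cfg$sigma_add * noise_draws[3:4]
  x_next <- x_n + cfg$gains * (1 + nu) * u + eta
  if (any(x_next <= 0))
    stop_stridegem(
      sprintf("stride map left the positive orthant: (T, L) = (%g, %g)",
              x_next[1], x_next[2]),
      "nonpositive_state")
  x_next
}

#' Simulate one trial of the stride map under a controller
#'
#' Starts at the operating point `x_0 = (Tstar, Lstar)` and iterates
#' [optimal_control_input()] and [stride_map_step()] for `n_strides`
#' strides. The belt-constraint check is performed on the result and
#' attached as attribute `"belt_check"`.
#'
#' @param cfg A [controller_config()].
#' @param rep_index Replicate index; with a non-`NULL` `cfg$seed` the RNG
#'   stream is derived from `(seed, rep_index)` so each rep is
#'   independently reproducible.
#' @param d_max Half belt length for the attached check (default 0.864).
#' @return A [stride_series()] with condition set to the variant name.
#' @export
simulate_walker <- function(cfg, rep_index = 1L, d_max = 0.864) {
  stopifnot(inherits(cfg, "controller_config"))
  seed <- if (is.null(cfg$seed)) NULL else derive_seed(cfg$seed, rep_index)
  with_seed(seed, {
    x <- c(cfg$Tstar, cfg$Lstar)
    out_T <- numeric(cfg$n_strides)
    out_L <- numeric(cfg$n_strides)
    for (n in seq_len(cfg$n_strides)) {
      u <- optimal_control_input(x, cfg)
      x <- stride_map_step(x, u, stats::rnorm(4), cfg)
      out_T[n] <- x[1]
      out_L[n] <- x[2]
    }
    s <- stride_series(T = out_T, L = out_L, v = cfg$v,
                       trial_id = sprintf("%s-rep%03d", cfg$variant,
                                          rep_index),
                       condition = cfg$variant)
    attr(s, "belt_check") <- check_belt_constraint(s, d_max)
    s
  })
}

#' Run a simulated model experiment
#'
#' Simulates `cfg$n_reps` replicate trials, applies the same per-trial
#' analysis used for experimental data (summary statistics, a per-rep GEM
#' frame, DFA on the tangent and perpendicular deviation series), and
#' aggregates across reps with means and 95% t-based confidence
#' intervals. A one-way two-group F test compares `SD(delta_T)` vs
#' `SD(delta_P)` and `alpha(delta_T)` vs `alpha(delta_P)` across reps.
#'
#' When `reject_walkoff = TRUE` (default), a replicate whose net
#' cumulative displacement would leave the belt is discarded and
#' regenerated from the next derived sub-seed (attempt-capped), so every
#' analyzed run -- like every run reported for the original models --
#' satisfies the belt constraint.
#'
#' @param cfg A [controller_config()].
#' @param d_max Half belt length (default 0.864).
#' @param reject_walkoff Regenerate belt-violating reps (default `TRUE`).
#' @param max_attempts Attempt cap per rep when rejecting (default 100).
#' @return An object of class `model_experiment`: list with `per_rep`
#'   (data.frame, one row per rep), `aggregate` (data.frame of means and
#'   CI half-widths), `anova_sd`, `anova_alpha` (see [direction_anova()]),
#'   `belt` (max |d_net| and rejection count), and `config`.
#' @export
run_model_experiment <- function(cfg, d_max = 0.864,
                                 reject_walkoff = TRUE,
                                 max_attempts = 100L) {
  stopifnot(inherits(cfg, "controller_config"))
  if (cfg$n_reps < 2L)
    stop_stridegem("need n_reps >= 2 for a model experiment",
                   "invalid_config")
  rows <- vector("list", cfg$n_reps)
  n_regenerated <- 0L
  max_abs_dnet <- 0
  for (r in seq_len(cfg$n_reps)) {
    s <- NULL
    for (att in 0:(max_attempts - 1L)) {
      cand_cfg <- cfg
      if (!is.null(cfg$seed) && att > 0L)
        cand_cfg$seed <- derive_seed(cfg$seed, 0L, att)
      cand <- simulate_walker(cand_cfg, rep_index = r, d_max = d_max)
      if (!reject_walkoff || attr(cand, "belt_check")$ok) { s <- cand; break }
      n_regenerated <- n_regenerated + 1L
    }
    if (is.null(s))
      stop_stridegem(
        sprintf("rep %d: no belt-respecting run within %d attempts",
                r, max_attempts),
        "constraint_unsatisfiable")
    bc <- attr(s, "belt_check")
    max_abs_dnet <- max(max_abs_dnet, abs(bc$max_d), abs(bc$min_d))
    S <- stride_speeds(s)
    frame <- fit_gem_frame(s)
    dev <- gem_decompose(s, frame)
    rows[[r]] <- data.frame(
      rep = r,
      mean_T = mean(s$T), mean_L = mean(s$L), mean_S = mean(S),
      sd_T = stats::sd(s$T), sd_L = stats::sd(s$L), sd_S = stats::sd(S),
      alpha_T = dfa(s$T)$alpha, alpha_L = dfa(s$L)$alpha,
      alpha_S = dfa(S)$alpha,
      sd_delta_T = stats::sd(dev$delta_T),
      sd_delta_P = stats::sd(dev$delta_P),
      alpha_delta_T = dfa(dev$delta_T)$alpha,
      alpha_delta_P = dfa(dev$delta_P)$alpha,
      max_d = bc$max_d, min_d = bc$min_d,
      belt_ok = bc$ok)
  }
  per_rep <- do.call(rbind, rows)
  vars <- setdiff(names(per_rep), c("rep", "belt_ok"))
  aggregate <- data.frame(
    measure = vars,
    mean = vapply(per_rep[vars], mean, numeric(1)),
    ci95 = vapply(per_rep[vars], ci95_halfwidth, numeric(1)),
    row.names = NULL)
  structure(
    list(per_rep = per_rep, aggregate = aggregate,
         anova_sd = direction_anova(per_rep$sd_delta_T,
                                    per_rep$sd_delta_P),
         anova_alpha = direction_anova(per_rep$alpha_delta_T,
                                       per_rep$alpha_delta_P),
         belt = list(max_abs_dnet = max_abs_dnet,
                     n_regenerated = n_regenerated,
                     d_max = d_max,
                     reject_walkoff = reject_walkoff),
         config = cfg),
    class = "model_experiment")
}

#' @export
print.model_experiment <- function(x, ...) {
  cat(sprintf("<model_experiment> %s: %d reps x %d strides\n",
              x$config$variant, x$config$n_reps, x$config$n_strides))
  ag <- x$aggregate
  pick <- ag$measure %in% c("sd_delta_T", "sd_delta_P",
                            "alpha_delta_T", "alpha_delta_P")
  for (i in which(pick))
    cat(sprintf("  %-14s %.4f +/- %.4f\n", ag$measure[i], ag$mean[i],
                ag$ci95[i]))
  cat(sprintf("  direction F (SD): %.2f, F (alpha): %.2f; max |d_net| = %.3f m\n",
              x$anova_sd$F, x$anova_alpha$F, x$belt$max_abs_dnet))
  invisible(x)
}
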