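# Shared fixtures and independent oracles, built in code at test time.

# A positive, strongly persistent stride series (fGn-based, not a
# controller simulation) for surrogate and DFA checks.
make_persistent_series <- function(n = 256L, seed = 11L, v = 1.21) {
  stride_series(T = 1.105 + 0.02 * generate_fgn(0.9, n, seed = seed),
                L = 1.337 + 0.015 * generate_fgn(0.9, n, seed = seed + 1L),
                v = v, trial_id = "persistent-fixture",
                condition = "synthetic")
}

# Independent brute-force oracle for the controller: evaluates the written
# expected cost under the controller's internal (unit-gain) plant model and
# minimizes it along the expected-goal-error constraint line by 1-D search.
expected_cost_oracle <- function(u, x, cfg) {
  a <- c(-cfg$v, 1)
  e0 <- sum(a * x)
  p0 <- x - c(cfg$Tstar, cfg$Lstar)
  s2m <- cfg$sigma_mult^2
  s2a <- cfg$sigma_add^2
  Ee2 <- (e0 + sum(a * u))^2 + sum(a^2 * s2m * u^2) + sum(a^2 * s2a)
  Ep2 <- sum((p0 + u)^2) + sum(s2m * u^2) + sum(s2a)
  cfg$w_e * Ee2 + cfg$w_p * Ep2 + sum(cfg$w_u * u^2)
}

brute_force_u <- function(x, cfg) {
  a <- c(-cfg$v, 1)
  e0 <- sum(a * x)
  u0 <- -e0 * a / sum(a^2)        # particular solution of a.u = -e0
  w <- c(1, cfg$v) / sqrt(1 + cfg$v^2)  # null space of a
  f <- function(t) expected_cost_oracle(u0 + t * w, x, cfg)
  t_opt <- stats::optimize(f, c(-5, 5), tol = 1e-12)$minimum
  u0 + t_opt * w
}
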