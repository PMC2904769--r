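test_that("control input vanishes at the operating point and on the MIP GEM", {
  for (variant in c("MIP", "POP", "OVC")) {
    cfg <- controller_config(variant)
    u <- optimal_control_input(c(cfg$Tstar, cfg$Lstar), cfg)
    expect_equal(u, c(0, 0), tolerance = 1e-12)
  }
  # strict MIP exerts no effort anywhere on the GEM (neutral stability)
  mip <- controller_config("MIP")
  for (T in c(0.9, 1.105, 1.3)) {
    u <- optimal_control_input(c(T, mip$v * T), mip)
    expect_equal(u, c(0, 0), tolerance = 1e-12)
  }
  # POP does exert effort along the GEM away from the operating point
  pop <- controller_config("POP")
  expect_gt(sum(optimal_control_input(c(1.3, pop$v * 1.3), pop)^2), 1e-6)
})

test_that("closed-form input matches the brute-force expected-cost minimizer", {
  set.seed(71)
  for (variant in c("MIP", "POP", "OVC")) {
    cfg <- controller_config(variant)
    for (i in 1:50) {
      x <- c(cfg$Tstar, cfg$Lstar) + rnorm(2, sd = 0.05)
      u_cf <- optimal_control_input(x, cfg)
      u_bf <- brute_force_u(x, cfg)
      expect_equal(u_cf, u_bf, tolerance = 1e-6)
      # and the closed form is no worse than the searched optimum
      expect_lte(expected_cost_oracle(u_cf, x, cfg),
                 expected_cost_oracle(u_bf, x, cfg) + 1e-9)
    }
  }
})

test_that("stride map step obeys its deterministic identities", {
  cfg <- controller_config("POP")
  x <- c(1.1, 1.35)
  expect_equal(stride_map_step(x, c(0, 0), rep(0, 4), cfg), x)
  cfg_unit <- controller_config("POP")  # G = I for POP
  u <- c(0.01, -0.02)
  expect_equal(stride_map_step(x, u, rep(0, 4), cfg_unit), x + u)
  ovc <- controller_config("OVC")
  expect_equal(stride_map_step(x, u, rep(0, 4), ovc), x + 1.24 * u)
  expect_error(stride_map_step(c(0.01, 0.01), c(-1, -1), rep(0, 4), cfg),
               class = "stridegem_nonpositive_state")
})

test_that("zero-noise simulations are constant at the operating point", {
  for (variant in c("MIP", "POP", "OVC")) {
    cfg <- controller_config(variant, sigma_mult = c(0, 0),
                             sigma_add = c(0, 0), n_strides = 20L,
                             seed = 1L)
    s <- simulate_walker(cfg)
    expect_equal(s$T, rep(cfg$Tstar, 20), tolerance = 1e-12)
    expect_equal(s$L, rep(cfg$Lstar, 20), tolerance = 1e-12)
  }
})

test_that("simulations are bitwise reproducible under a fixed seed", {
  cfg <- controller_config("OVC", n_strides = 100L, seed = 77L)
  a <- simulate_walker(cfg, rep_index = 2L)
  b <- simulate_walker(cfg, rep_index = 2L)
  expect_identical(a$T, b$T)
  expect_identical(a$L, b$L)
  c_ <- simulate_walker(cfg, rep_index = 3L)
  expect_false(identical(a$T, c_$T))  # reps draw independent streams
})

test_that("model experiment reproduces the direction contrast of each variant", {
  mip <- run_model_experiment(controller_config("MIP", n_reps = 8L,
                                                seed = 81L))
  ag <- function(e, m) e$aggregate$mean[e$aggregate$measure == m]
  # variability tightly compressed along the GEM: SD(delta_T) >> SD(delta_P)
  expect_gt(ag(mip, "sd_delta_T") / ag(mip, "sd_delta_P"), 3)
  expect_lt(mip$anova_sd$p, 1e-6)
  expect_identical(mip$anova_sd$df, c(1L, 14L))
  # Brownian drift along the GEM
  expect_equal(ag(mip, "alpha_delta_T"), 1.5, tolerance = 0.15)
  expect_true(all(mip$per_rep$belt_ok))

  ovc <- run_model_experiment(controller_config("OVC", n_reps = 8L,
                                                seed = 82L))
  expect_lt(ag(ovc, "alpha_delta_P"), 0.5)
  expect_gt(ag(ovc, "alpha_delta_T"), ag(ovc, "alpha_delta_P"))
})

test_that("perpendicular persistence decreases with plant gain", {
  alphas <- vapply(c(0.8, 1.0, 1.24), function(g) {
    e <- run_model_experiment(
      controller_config("POP", gains = c(g, g), n_reps = 8L, seed = 83L))
    e$aggregate$mean[e$aggregate$measure == "alpha_delta_P"]
  }, numeric(1))
  expect_false(is.unsorted(rev(alphas), strictly = TRUE))  # decreasing in g
  expect_equal(alphas[2], 0.5, tolerance = 0.1)  # unit gain: uncorrelated
  expect_gt(alphas[1], 0.5)   # under-correction: persistent
  expect_lt(alphas[3], 0.5)   # over-correction: anti-persistent
})

test_that("controller configuration rejects non-coercive or invalid weights", {
  expect_error(controller_config("MIP", w_e = 0),
               class = "stridegem_invalid_config")
  expect_error(controller_config("MIP", w_p = 0, w_u = c(0, 0)),
               class = "stridegem_invalid_config")
  expect_error(controller_config("POP", sigma_mult = c(-0.1, 0.01)),
               class = "stridegem_invalid_config")
  # preset parameter values are the documented ones
  pop <- controller_config("POP")
  expect_equal(pop$w_p, 2.79)
  expect_equal(pop$Lstar, pop$v * pop$Tstar)
  expect_equal(controller_config("OVC")$gains, c(1.24, 1.24))
  expect_equal(controller_config("MIP")$w_p, 0)
})
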