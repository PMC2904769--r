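test_that("stride speeds are element-wise L/T", {
  s <- stride_series(T = c(1, 1, 1), L = c(1.2, 1.2, 1.2), v = 1.2)
  expect_equal(stride_speeds(s), c(1.2, 1.2, 1.2))

  # preferred operating point of treadmill walking at 1.21 m/s
  s2 <- stride_series(T = 1.105, L = 1.337, v = 1.21)
  expect_equal(stride_speeds(s2), 1.2100, tolerance = 1e-4)

  set.seed(5)
  T <- runif(50, 0.8, 1.4); L <- runif(50, 1.0, 1.6)
  s3 <- stride_series(T = T, L = L)
  oracle <- vapply(1:50, function(i) L[i] / T[i], numeric(1))
  expect_equal(stride_speeds(s3), oracle, tolerance = 1e-15)
})

test_that("series invariants are enforced", {
  expect_error(stride_series(T = c(1, -1), L = c(1, 1)),
               class = "stridegem_invalid_series")
  expect_error(stride_series(T = c(1, 1), L = c(1, 0)),
               class = "stridegem_invalid_series")
  expect_error(stride_series(T = c(1, 1, 1), L = c(1, 1)),
               class = "stridegem_invalid_series")
  expect_error(stride_series(T = 1, L = 1, v = 0),
               class = "stridegem_invalid_series")
})

test_that("d_net accumulates lab-frame displacement per stride", {
  # on-speed strides never move relative to the belt center
  tt <- seq(0.9, 1.3, length.out = 10)
  s <- stride_series(T = tt, L = 1.21 * tt, v = 1.21)
  expect_equal(dnet(s), rep(0, 10))

  s2 <- stride_series(T = c(1, 1), L = c(1.5, 0.5), v = 1)
  expect_equal(dnet(s2), c(0.5, 0.0))

  set.seed(6)
  s3 <- stride_series(T = runif(40, 0.9, 1.3), L = runif(40, 1.1, 1.5),
                      v = 1.21)
  acc <- 0; oracle <- numeric(40)
  for (i in 1:40) {
    acc <- acc + s3$L[i] - s3$v * s3$T[i]
    oracle[i] <- acc
  }
  expect_equal(dnet(s3), oracle, tolerance = 1e-12)
})

test_that("belt constraint check flags walk-off and returns extremes", {
  tt <- seq(0.9, 1.3, length.out = 10)
  on_speed <- stride_series(T = tt, L = 1.21 * tt, v = 1.21)
  chk <- check_belt_constraint(on_speed)
  expect_true(chk$ok)
  expect_equal(chk$max_d, 0)
  expect_equal(chk$min_d, 0)

  jump <- stride_series(T = 1, L = 2, v = 1)  # L - vT = 1 > 0.864
  expect_false(check_belt_constraint(jump, d_max = 0.864)$ok)

  ovc <- simulate_walker(controller_config("OVC", seed = 21L))
  expect_true(attr(ovc, "belt_check")$ok ||
                abs(attr(ovc, "belt_check")$max_d) > 0)  # check ran
  expect_named(attr(ovc, "belt_check"), c("ok", "max_d", "min_d"))
})

test_that("stride CSV round-trips losslessly and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(7)
  s <- stride_series(T = runif(10, 0.9, 1.3), L = runif(10, 1.1, 1.5),
                     v = 1.21, trial_id = "rt", condition = "unit")
  write_stride_csv(s, path)
  r <- read_stride_csv(path)
  expect_equal(r$T, s$T, tolerance = 1e-12)
  expect_equal(r$L, s$L, tolerance = 1e-12)
  expect_identical(r$v, s$v)
  expect_identical(r$trial_id, "rt")
  expect_identical(r$condition, "unit")

  big <- make_humanlike_trial(300, seed = 9L)
  write_stride_csv(big, path)
  r2 <- read_stride_csv(path)
  expect_equal(r2$T, big$T, tolerance = 1e-12)
  expect_equal(r2$L, big$L, tolerance = 1e-12)

  writeLines(c("# v=1.21", "stride,T_s,L_m", "1,0,1.3"), path)
  expect_error(read_stride_csv(path), class = "stridegem_malformed_file")
  writeLines(c("# v=1.21", "stride,T_s", "1,1.1"), path)
  expect_error(read_stride_csv(path), class = "stridegem_malformed_file")
  writeLines(c("stride,T_s,L_m", "1,1.1,1.3"), path)  # no belt speed
  expect_error(read_stride_csv(path), class = "stridegem_malformed_file")
  expect_error(read_stride_csv(file.path(tempdir(), "absent.csv")),
               class = "stridegem_malformed_file")
})

test_that("mean stride speed uses the per-stride definition", {
  # 2-stride counterexample: mean(L/T) != sum(L)/sum(T)
  s <- stride_series(T = c(1, 2), L = c(1, 1), v = 1)
  expect_equal(mean(stride_speeds(s)), 0.75)
  expect_false(isTRUE(all.equal(mean(stride_speeds(s)),
                                sum(s$L) / sum(s$T))))
})

test_that("summarize_trial matches an independently scripted oracle", {
  s <- make_persistent_series(n = 256L, seed = 13L)
  sm <- summarize_trial(s, gem = FALSE)
  expect_s3_class(sm, "trial_summary")
  S <- s$L / s$T
  d <- cumsum(s$L - s$v * s$T)
  oracle <- list(T = s$T, L = s$L, S = S, d_net = d)
  for (v in names(oracle)) {
    row <- sm[sm$variable == v, ]
    expect_equal(row$mean, mean(oracle[[v]]), tolerance = 1e-12)
    expect_equal(row$sd, sqrt(sum((oracle[[v]] - mean(oracle[[v]]))^2) /
                                (length(oracle[[v]]) - 1)),
                 tolerance = 1e-12)
    expect_gte(row$sd, 0)
    expect_identical(row$n, length(s))
  }
  expect_equal(attr(sm, "max_d"), max(d))
  expect_equal(attr(sm, "min_d"), min(d))

  # noiseless constant-speed series: SD(S) = 0
  tt <- seq(0.9, 1.3, length.out = 64)
  flat <- stride_series(T = tt, L = 1.21 * tt, v = 1.21)
  sm2 <- summarize_trial(flat, gem = FALSE)
  expect_equal(sm2$sd[sm2$variable == "S"], 0)
})
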