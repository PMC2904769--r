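test_that("independent shuffle preserves each value multiset and kills persistence", {
  s <- make_persistent_series(n = 256L, seed = 21L)
  set.seed(1)
  sh <- shuffle_surrogate(s)
  expect_identical(sort(sh$T), sort(s$T))
  expect_identical(sort(sh$L), sort(s$L))
  expect_equal(mean(sh$T), mean(s$T))
  expect_equal(sd(sh$L), sd(s$L))

  # temporal order destroyed: alpha of shuffled T ~ 1/2 on persistent input
  expect_gt(dfa(s$T)$alpha, 0.7)
  set.seed(2)
  alphas <- vapply(1:20, function(i) dfa(shuffle_surrogate(s)$T)$alpha,
                   numeric(1))
  expect_equal(mean(alphas), 0.5, tolerance = 0.1)

  one <- stride_series(T = 1.1, L = 1.3)
  expect_identical(shuffle_surrogate(one)$T, one$T)
})

test_that("paired shuffle preserves the (T, L) pair multiset and variance ratio", {
  s <- make_persistent_series(n = 200L, seed = 23L)
  set.seed(3)
  ps <- paired_shuffle_surrogate(s)
  expect_identical(sort(paste(s$T, s$L)), sort(paste(ps$T, ps$L)))
  expect_identical(sort(stride_speeds(ps)), sort(stride_speeds(s)))

  # same frame, same point cloud: SD ratio preserved exactly
  f <- fit_gem_frame(s)
  d0 <- gem_decompose(s, f)
  d1 <- gem_decompose(ps, f)
  expect_equal(sd(d1$delta_T) / sd(d1$delta_P),
               sd(d0$delta_T) / sd(d0$delta_P), tolerance = 1e-12)

  # stride-speed persistence destroyed
  set.seed(4)
  alphas <- vapply(1:20, function(i)
    dfa(stride_speeds(paired_shuffle_surrogate(s)))$alpha, numeric(1))
  expect_equal(mean(alphas), 0.5, tolerance = 0.1)
})

test_that("phase randomization preserves the spectrum, mean and SD", {
  for (n in c(255L, 256L)) {       # odd and even lengths
    x <- 1.1 + 0.02 * generate_fgn(0.8, n, seed = 31L + n)
    set.seed(5)
    y <- phase_randomized_surrogate(x)
    expect_equal(mean(y), mean(x), tolerance = 1e-10)
    expect_equal(sd(y), sd(x), tolerance = 1e-6 * sd(x))
    px <- Mod(fft(x - mean(x)))^2
    py <- Mod(fft(y - mean(y)))^2
    expect_equal(py[-1], px[-1], tolerance = 1e-8)
    expect_false(isTRUE(all.equal(y, x)))  # phases actually randomized
  }
  expect_error(phase_randomized_surrogate(rnorm(7)),
               class = "stridegem_invalid_series")
})

test_that("phase randomization approximately preserves the DFA exponent", {
  x <- generate_fgn(0.8, 512, seed = 41L)
  a0 <- dfa(x)$alpha
  set.seed(6)
  as <- vapply(1:10, function(i) dfa(phase_randomized_surrogate(x))$alpha,
               numeric(1))
  expect_lt(abs(mean(as) - a0), 0.15)
})

test_that("valid-surrogate generation respects belt and positivity constraints", {
  # constant on-speed trial: permutations are the identity, no drift
  zd <- stride_series(T = rep(1.1, 100), L = rep(1.21 * 1.1, 100),
                      v = 1.21)
  set <- generate_valid_surrogates(
    zd, surrogate_config("shuffle", n_surrogates = 10L, seed = 51L))
  expect_length(set$surrogates, 10L)
  expect_true(all(set$report$attempts == 1L))
  expect_identical(set$report$rejected_belt, 0L)

  # paired shuffling of an on-speed trial cannot create drift: every
  # (T, L) pair satisfies L = vT, so d_net stays identically zero
  tt <- rep(c(1.0, 1.2), 50)
  zd2 <- stride_series(T = tt, L = 1.21 * tt, v = 1.21)
  set2 <- generate_valid_surrogates(
    zd2, surrogate_config("paired_shuffle", n_surrogates = 10L,
                          seed = 51L))
  expect_true(all(set2$report$attempts == 1L))
  for (sg in set2$surrogates)
    expect_true(all(abs(dnet(sg)) < 1e-12))

  # all three kinds on a humanlike trial: every surrogate stays on belt
  hl <- make_humanlike_trial(250, seed = 52L)
  for (kind in c("shuffle", "phase_randomized", "paired_shuffle")) {
    st <- generate_valid_surrogates(
      hl, surrogate_config(kind, n_surrogates = 5L, seed = 53L))
    for (sg in st$surrogates) {
      expect_true(check_belt_constraint(sg)$ok)
      expect_true(all(sg$T > 0) && all(sg$L > 0))
    }
  }

  # adversarial: original cancels drift stride-by-stride, but permutations
  # produce a random walk that exceeds a tight d_max almost surely
  dev <- rep(c(0.2, -0.2), 100)
  adv <- stride_series(T = rep(1, 200), L = 1.21 + dev, v = 1.21)
  expect_true(check_belt_constraint(adv, d_max = 0.25)$ok)
  expect_error(
    generate_valid_surrogates(
      adv, surrogate_config("shuffle", n_surrogates = 2L, d_max = 0.25,
                            max_attempts_per_surrogate = 5L, seed = 54L)),
    class = "stridegem_constraint_unsatisfiable")

  # original violating the constraint is rejected up front
  viol <- make_adversarial_trials()$belt_violating
  expect_error(generate_valid_surrogates(viol, surrogate_config("shuffle")),
               class = "stridegem_invalid_series")
})

test_that("surrogate generation is reproducible under a fixed seed", {
  s <- make_humanlike_trial(220, seed = 61L)
  cfg <- surrogate_config("phase_randomized", n_surrogates = 3L, seed = 62L)
  a <- generate_valid_surrogates(s, cfg)
  b <- generate_valid_surrogates(s, cfg)
  for (i in 1:3) {
    expect_identical(a$surrogates[[i]]$T, b$surrogates[[i]]$T)
    expect_identical(a$surrogates[[i]]$L, b$surrogates[[i]]$L)
  }
})
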