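test_that("the mean release curve follows the Weibull model", {
  prm <- release_params(f_inf = 100, tau = 3, beta = 1)
  m <- mean_curve(prm, vg_times)
  expect_equal(m, 100 * (1 - exp(-vg_times / 3)), tolerance = 1e-12)
  expect_equal(m[1], 96.43, tolerance = 1e-3)
  expect_equal(m[2], 99.33, tolerance = 1e-3)
  # small-time limit: m -> 0
  expect_lt(mean_curve(prm, c(1e-6, 1, 2))[1], 1e-4)
})

test_that("the post-peak decline is linear from the first near-plateau time", {
  prm <- release_params(f_inf = 100, tau = 3, beta = 1, decay = 0.05)
  w <- 100 * (1 - exp(-vg_times / 3))
  # w(10) = 96.4 already exceeds 95% of f_inf, so decline starts at 10 min
  expect_equal(mean_curve(prm, vg_times), w - 0.05 * (vg_times - 10),
               tolerance = 1e-12)
  # ~1.5% drop attributable to decay between 15 and 45 min
  m <- mean_curve(prm, vg_times)
  expect_equal((m[2] - m[5]) - (w[2] - w[5]), 0.05 * 30, tolerance = 1e-12)
  # slow release never reaching the plateau on the grid: no decline applied
  slow <- release_params(f_inf = 100, tau = 100, beta = 1, decay = 0.5)
  expect_equal(mean_curve(slow, c(10, 20, 30)),
               100 * (1 - exp(-c(10, 20, 30) / 100)), tolerance = 1e-12)
})

test_that("the noiseless curve is monotone and bounded without decay", {
  set.seed(51)
  for (k in 1:20) {
    prm <- release_params(f_inf = runif(1, 50, 110), tau = runif(1, 1, 30),
                          beta = runif(1, 0.5, 3))
    m <- mean_curve(prm, sort(sample(1:90, 5)))
    expect_true(all(diff(m) >= 0))
    expect_true(all(m <= prm$f_inf & m >= 0))
  }
})

test_that("profile generation is seeded, truncated and exact when noiseless", {
  prm <- release_params(f_inf = 99, tau = 3, decay = 0.04,
                        noise_sd = c(0.9, 0.94, 0.94, 0.91, 0.97))
  p1 <- generate_profile(prm, vg_times, "A", seed = 7)
  p2 <- generate_profile(prm, vg_times, "A", seed = 7)
  p3 <- generate_profile(prm, vg_times, "A", seed = 8)
  expect_identical(p1$replicates, p2$replicates)
  expect_false(identical(p1$replicates, p3$replicates))
  expect_equal(dim(p1$replicates), c(5L, 3L))

  quiet <- release_params(f_inf = 99, tau = 3, decay = 0.04, noise_sd = 0)
  p0 <- generate_profile(quiet, vg_times, "A", seed = 1)
  expect_equal(p0$replicates[, 1], mean_curve(quiet, vg_times),
               tolerance = 1e-12)
  expect_identical(p0$replicates[, 1], p0$replicates[, 3])

  # heavy noise on a tiny release is truncated at zero, never negative
  tiny <- release_params(f_inf = 1, tau = 1e4, noise_sd = 5, n_reps = 20)
  pt <- generate_profile(tiny, c(5, 10, 15), "A", seed = 3)
  expect_true(all(pt$replicates >= 0))
  expect_true(any(pt$replicates == 0))

  # seed is mandatory and the caller's RNG stream is untouched
  expect_error(generate_profile(prm, vg_times, "A"), "seed")
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_profile(prm, vg_times, "A", seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("replicate noise reproduces its nominal SD in the long run", {
  prm <- release_params(f_inf = 99, tau = 3, noise_sd = 1, n_reps = 3)
  devs <- unlist(lapply(1:1000, function(s) {
    p <- generate_profile(prm, c(10, 20, 30), "A", seed = s)
    p$replicates - mean_curve(prm, c(10, 20, 30))
  }))
  expect_equal(sd(devs), 1, tolerance = 0.05)
})

test_that("study generation perturbs kinetics per test product", {
  quiet <- release_params(f_inf = 99, tau = 3, decay = 0.04, noise_sd = 0)
  st <- generate_study(quiet, list(A = numeric(0), B = numeric(0)),
                       vg_times, seed = 5)
  cmp <- compare_dissolution(st)
  expect_equal(cmp$results$f1, c(0, 0))
  expect_equal(cmp$results$f2, c(100, 100))

  # a ~12% downward shift in f_inf flips the verdict, ~5% does not
  st2 <- generate_study(quiet, list(near = c(f_inf = -5),
                                    far = c(f_inf = -12)),
                        vg_times, seed = 5)
  r <- compare_dissolution(st2)$results
  expect_identical(r$verdict, c("similar", "not_similar"))

  expect_error(generate_study(quiet, list(c(speed = 2)), vg_times, seed = 1),
               "unknown kinetic")
  expect_error(dissim:::perturb_params(quiet, c(5)), "named")

  # bit-reproducible for a fixed seed
  sa <- generate_study(quiet, list(A = c(tau = 0.5)), vg_times, seed = 11)
  sb <- generate_study(quiet, list(A = c(tau = 0.5)), vg_times, seed = 11)
  expect_identical(sa$reference$replicates, sb$reference$replicates)
  expect_identical(sa$tests$A$replicates, sb$tests$A$replicates)
})

test_that("the packaged preset describes a plausible fast-release study", {
  pre <- release_preset("vildagliptin50")
  expect_equal(pre$times, vg_times)
  expect_equal(pre$params$n_reps, 3L)
  expect_length(pre$test_deltas, 6)
  expect_true(all(pre$params$noise_sd >= 0.6 & pre$params$noise_sd <= 3.5))
  st <- generate_study(pre$params, pre$test_deltas, pre$times, seed = 2)
  expect_length(st$tests, 6)
  expect_error(release_preset("no_such_preset"), "available")
})

test_that("peak-area generation inverts the quantitation exactly", {
  for (repl in c("replaced", "not_replaced")) {
    cfg <- default_quant(replacement = repl)
    prm <- release_params(f_inf = 99, tau = 3, decay = 0.04,
                          noise_sd = c(0.9, 0.94, 0.94, 0.91, 0.97))
    p <- generate_profile(prm, vg_times, "A", seed = 13)
    at <- generate_area_table(p, cfg)
    back <- percent_released(at, cfg, "A")
    expect_lt(max(abs(back$replicates - p$replicates)), 1e-9)
  }

  # no withdrawal: areas directly proportional to % released
  cfg0 <- default_quant(withdrawal_vol_ml = 0)
  p <- generate_profile(release_params(90, 5, noise_sd = 0), c(10, 20, 30),
                        "A", seed = 1)
  at0 <- generate_area_table(p, cfg0)
  ratio <- at0$sample_areas / p$replicates
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))

  # a collapsing profile implies a negative vessel concentration
  bad <- dissolution_profile("X", c(10, 20, 30),
                             replicates = cbind(c(100, 1, 1)))
  expect_error(generate_area_table(bad, default_quant()), "concentration")
})

test_that("a flat profile implies diluting vs conserved concentrations", {
  flat <- dissolution_profile("F", vg_times,
                              replicates = matrix(100, 5, 1))
  # medium replacement dilutes the vessel: recovered areas must fall
  a_rep <- generate_area_table(flat, default_quant())$sample_areas[, 1]
  expect_true(all(diff(a_rep) < 0))
  # without replacement the concentration is conserved
  a_not <- generate_area_table(
    flat, default_quant(replacement = "not_replaced"))$sample_areas[, 1]
  expect_equal(diff(a_not), rep(0, 4), tolerance = 1e-9)
})
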