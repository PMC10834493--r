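test_that("f1 and f2 recover the published values for each generic", {
  for (p in paste0("V-", 1:6)) {
    expect_equal(difference_factor(vg_means$Ref, vg_means[[p]]),
                 vg_f1[[p]], tolerance = 0.01)
    expect_equal(similarity_factor(vg_means$Ref, vg_means[[p]]),
                 vg_f2[[p]], tolerance = 0.02 / vg_f2[[p]])
  }
})

test_that("identical profiles give the exact boundary values", {
  x <- c(40.5, 71.2, 88.8, 95.1, 99.0)
  expect_identical(difference_factor(x, x), 0)
  expect_equal(similarity_factor(x, x), 100)   # 50*log10(100) exactly
})

test_that("uniform shifts follow the closed forms", {
  # constant reference 90 over 5 points, test shifted by +5
  expect_equal(difference_factor(rep(90, 5), rep(95, 5)),
               100 * 25 / 450, tolerance = 1e-12)
  # f2 under shift delta: 50*log10(100/sqrt(1+delta^2)), any n
  for (delta in c(0.1, 1, 5, 10, 20)) {
    for (n in c(3, 5, 10)) {
      ref <- seq(60, 95, length.out = n)
      expect_equal(similarity_factor(ref, ref + delta),
                   50 * log10(100 / sqrt(1 + delta^2)), tolerance = 1e-12)
    }
  }
  expect_equal(50 * log10(100 / sqrt(1 + 25)), 64.6256, tolerance = 1e-4)
})

test_that("f2 is symmetric while f1 is not, and both are monotone in shift", {
  set.seed(41)
  for (k in 1:25) {
    R <- runif(5, 50, 100)
    T_ <- runif(5, 50, 100)
    expect_equal(similarity_factor(R, T_), similarity_factor(T_, R),
                 tolerance = 1e-12)
    if (abs(sum(R) - sum(T_)) > 1e-8)
      expect_false(isTRUE(all.equal(difference_factor(R, T_),
                                    difference_factor(T_, R))))
  }
  R <- vg_means$Ref
  shifts <- c(0.5, 1, 2, 5, 8, 12)
  f1s <- vapply(shifts, function(d) difference_factor(R, R + d), 0)
  f2s <- vapply(shifts, function(d) similarity_factor(R, R + d), 0)
  expect_true(all(diff(f1s) > 0))
  expect_true(all(diff(f2s) < 0))
})

test_that("factor computation rejects incomparable series", {
  expect_error(difference_factor(1:5, 1:4), "different numbers")
  expect_error(similarity_factor(1:5, 1:4), "different numbers")
  expect_error(difference_factor(rep(0, 5), rep(1, 5)), "undefined")
})

test_that("time-point selection implements the 85% truncation rule", {
  expect_equal(select_timepoints(c(40, 70, 88, 95, 99), "all"), 1:5)
  # fast release: 85% already exceeded at the first point -> keep two
  expect_equal(select_timepoints(vg_means$Ref, "until_85_plus_one"), 1:2)
  # crossing at the third point keeps one extra
  expect_equal(select_timepoints(c(40, 70, 88, 95, 99), "until_85_plus_one"),
               1:4)
  # never reaching 85% keeps everything
  expect_equal(select_timepoints(c(20, 40, 60, 75, 80), "until_85_plus_one"),
               1:5)
  # crossing at the last point: no extra available
  expect_equal(select_timepoints(c(40, 60, 75, 80, 90), "until_85_plus_one"),
               1:5)
})

test_that("equivalence assessment returns ordered verdicts per test", {
  cmp <- compare_dissolution(vg_study())
  expect_s3_class(cmp, "dissolution_comparison")
  r <- as.data.frame(cmp)
  expect_identical(r$test_label, paste0("V-", 1:6))
  expect_true(all(r$verdict == "similar"))
  expect_true(all(r$n_used == 5))
  expect_equal(cmp$times_used, vg_times)
  expect_equal(unname(coef(cmp)[, "f1"]), unname(vg_f1), tolerance = 0.01)

  # a 20% uniform excess is neither f1- nor f2-acceptable
  ref <- dissolution_profile("Ref", c(10, 20, 30), mean = c(60, 70, 75))
  hot <- dissolution_profile("T", c(10, 20, 30), mean = c(80, 90, 95))
  bad <- compare_dissolution(dissolution_study(ref, list(hot)))
  expect_identical(bad$results$verdict, "not_similar")
  expect_gt(bad$results$f1, 15)
  expect_lt(bad$results$f2, 50)
})

test_that("verdicts use unrounded factors and the configured rule", {
  # f2 barely below 50 (shift slightly over 10%) must fail the default rule
  ref <- dissolution_profile("Ref", c(10, 20, 30), mean = c(60, 70, 75))
  tst <- dissolution_profile("T", c(10, 20, 30), mean = c(60, 70, 75) + 10.1)
  st <- dissolution_study(ref, list(tst))
  cmp <- compare_dissolution(st)
  expect_lt(cmp$results$f2, 50)
  expect_identical(cmp$results$verdict, "not_similar")

  # conjunctive rule: f2 pass + f1 fail -> not similar; f2-only rule passes.
  # A one-sided spike on a low-valued reference inflates f1 (sum |diff| /
  # sum R) while leaving the mean squared difference moderate.
  ref2 <- dissolution_profile("Ref", c(10, 20, 30), mean = c(10, 20, 30))
  tst2 <- dissolution_profile("T", c(10, 20, 30), mean = c(20, 20, 30))
  st2 <- dissolution_study(ref2, list(tst2))
  both <- compare_dissolution(st2)$results
  f2only <- compare_dissolution(st2, rule = "f2_only")$results
  expect_gt(both$f1, 15)
  expect_gt(both$f2, 50)
  expect_identical(both$verdict, "not_similar")
  expect_identical(f2only$verdict, "similar")

  expect_error(compare_dissolution(st2, f2_min = 120), "f2_min")
  expect_error(compare_dissolution(st2, f1_max = -1), "f1_max")
})

test_that("truncation policy restricts the factor sums", {
  cmp <- compare_dissolution(vg_study(), policy = "until_85_plus_one")
  expect_equal(cmp$times_used, c(10, 15))
  expect_true(all(cmp$results$n_used == 2))
  r <- cmp$results
  expect_equal(r$f1[r$test_label == "V-2"],
               difference_factor(vg_means$Ref[1:2], vg_means$`V-2`[1:2]),
               tolerance = 1e-12)
})
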