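# BP estimators: ratiometric arithmetic, separable fits, round-trips.

test_that("ratio estimator is the exact single-point arithmetic", {
  m <- proportional_measurement(bp = 0)
  for (i in c(0L, 5L, 10L)) expect_equal(bp_ratio(m, i)$bp, 0)

  tt <- seq(0, 5, 0.5)
  m2 <- dual_probe_measurement(
    "s", "x",
    concentration_curve("targeted", tt, c(rep(100, 10), 30)),
    concentration_curve("untargeted", tt, c(rep(100, 10), 10)))
  expect_equal(bp_ratio(m2)$bp, 2.0)

  expect_error(bp_ratio(m2, 11L), "outside")
  m3 <- dual_probe_measurement(
    "s", "x",
    concentration_curve("targeted", tt, rep(1, 11)),
    concentration_curve("untargeted", tt, rep(0, 11)))
  expect_error(bp_ratio(m3), "unusable")
})

test_that("ratio recovers BP exactly under its own proportional model", {
  for (bp in c(0.1, 1, 2.5, 4)) {
    expect_equal(bp_ratio(proportional_measurement(bp))$bp, bp,
                 tolerance = 1e-12)
  }
})

test_that("washout-only fit recovers exact monoexponential data", {
  tt <- seq(0, 5, 0.5)
  f <- fit_untargeted_dpm(concentration_curve("untargeted", tt,
                                              150 * exp(-0.2 * tt)))
  expect_equal(f$rates$F, 0.2, tolerance = 1e-6)
  expect_equal(unname(f$amplitudes["free"]), 150, tolerance = 1e-6)

  fc <- fit_untargeted_dpm(concentration_curve("untargeted", tt,
                                               rep(42, 11)))
  expect_equal(fc$rates$F, 0, tolerance = 1e-9)

  expect_error(fit_untargeted_dpm(concentration_curve("untargeted", tt,
                                                      rep(0, 11))),
               "degenerate")
  expect_error(fit_untargeted_dpm(
    concentration_curve("targeted", tt, 150 * exp(-0.2 * tt))), "labeled")
})

test_that("washout rate is unbiased under measurement noise", {
  tt <- seq(0, 5, 0.5)
  clean <- 150 * exp(-0.2 * tt)
  sigma <- 0.0048 * sqrt(mean(clean^2))
  set.seed(21)
  Fs <- vapply(1:100, function(i) {
    y <- clean + rnorm(length(tt), 0, sigma)
    fit_untargeted_dpm(concentration_curve("untargeted", tt, y))$rates$F
  }, numeric(1))
  expect_lt(abs(mean(Fs) - 0.2) / 0.2, 0.02)
})

test_that("two-compartment targeted fit round-trips its own model", {
  r <- rate_constants(F = 0.2, k3 = 0.3, k4 = 0.1)
  m <- simulate_dual_probe(r, noise_percent = 0, seed = 1, variant = "DPM")
  f <- fit_targeted_dpm(m$targeted, F_fixed = 0.2)
  expect_equal(f$bp, 3, tolerance = 1e-3)
  expect_true(f$converged)

  # no specific binding: BP collapses to zero
  r0 <- rate_constants(F = 0.3, k3 = 0, k4 = 0.1)
  m0 <- simulate_dual_probe(r0, noise_percent = 0, seed = 1,
                            variant = "DPM")
  expect_lt(fit_targeted_dpm(m0$targeted, F_fixed = 0.3)$bp, 1e-6)
})

test_that("ignoring nonspecific binding biases the two-compartment fit", {
  # data generated WITH nonspecific binding, fit without it
  m <- simulate_dual_probe(study_rates(bp = 3), noise_percent = 0, seed = 1)
  f <- fit_dual_probe(m, "dpm", k4_fixed = 0.1)
  expect_gt(abs(f$bp - 3), 0.3)
})

test_that("untargeted DPM-NS fit recovers its generating rates", {
  r <- rate_constants(F = 0.2, k5 = 0.16, k6 = 0.06)
  m <- simulate_dual_probe(r, noise_percent = 0, seed = 1)
  f <- fit_untargeted_dpmns(m$untargeted)
  expect_rel_equal(unlist(f$rates[c("F", "k5", "k6")]),
                   c(0.2, 0.16, 0.06), 0.01)

  # degenerate limit: no nonspecific binding collapses the biexponential
  r0 <- rate_constants(F = 0.2)
  m0 <- simulate_dual_probe(r0, noise_percent = 0, seed = 1)
  f0 <- fit_untargeted_dpmns(m0$untargeted)
  expect_rel_equal(f0$rates$F, 0.2, 0.01)
  expect_lt(f0$rates$k5, 0.01)

  expect_error(
    fit_untargeted_dpmns(concentration_curve("untargeted", 0:3, rep(1, 4))),
    "at least 5")
})

test_that("noisy nonspecific ratio estimates center on the truth", {
  r <- study_rates(bp = 1)
  k56 <- vapply(1:60, function(i) {
    f <- fit_untargeted_dpmns(simulate_dual_probe(r, seed = 500 + i)$untargeted)
    f$rates$k5 / f$rates$k6
  }, numeric(1))
  expect_lt(abs(median(k56) - 8 / 3) / (8 / 3), 0.25)
})

test_that("targeted DPM-NS fit round-trips the tissue-average BP", {
  m <- simulate_dual_probe(study_rates(bp = 2.17), noise_percent = 0,
                           seed = 1)
  f <- fit_targeted_dpmns(m$targeted, F = 2, k5 = 0.16, k6 = 0.06)
  expect_equal(f$bp, 2.17, tolerance = 2.17 * 0.02)

  m0 <- simulate_dual_probe(study_rates(bp = 0), noise_percent = 0,
                            seed = 1)
  expect_lt(fit_targeted_dpmns(m0$targeted, F = 2, k5 = 0.16,
                               k6 = 0.06)$bp, 0.01)
})

test_that("targeted DPM-NS estimates are unbiased under noise", {
  bps <- vapply(1:100, function(i) {
    m <- simulate_dual_probe(study_rates(bp = 1), seed = 700 + i)
    fit_targeted_dpmns(m$targeted, F = 2, k5 = 0.16, k6 = 0.06)$bp
  }, numeric(1))
  expect_lt(abs(mean(bps) - 1), 0.1)
})

test_that("every model estimator round-trips random parameter draws", {
  set.seed(31)
  for (i in 1:20) {
    k4 <- runif(1, 0.02, 0.5)
    bp <- runif(1, 0.1, 4)
    r <- rate_constants(F = runif(1, 0.02, 0.5), k3 = bp * k4, k4 = k4,
                        k5 = runif(1, 0.02, 0.5), k6 = runif(1, 0.02, 0.5))
    mns <- simulate_dual_probe(r, noise_percent = 0, seed = i)
    expect_equal(fit_dual_probe(mns, "dpmns")$bp, bp, tolerance = bp * 0.02)
    mdp <- simulate_dual_probe(r, noise_percent = 0, seed = i,
                               variant = "DPM")
    expect_equal(fit_dual_probe(mdp, "dpm")$bp, bp, tolerance = bp * 0.02)
  }
})

test_that("modeling nonspecific binding beats the ratio when it is present", {
  for (bp in c(1, 3)) {
    m <- simulate_dual_probe(study_rates(bp), noise_percent = 0, seed = 2)
    err_ns <- abs(fit_dual_probe(m, "dpmns", k4_fixed = 0.1)$bp - bp)
    err_ratio <- abs(bp_ratio(m)$bp - bp)
    expect_lt(err_ns, err_ratio)
  }
})

test_that("fixing k4 reduces the targeted search to the k3 profile", {
  m <- simulate_dual_probe(study_rates(bp = 1), noise_percent = 0, seed = 3)
  f <- fit_dual_probe(m, "dpmns", k4_fixed = 0.1)
  expect_equal(f$rates$k4, 0.1)
  expect_equal(f$bp, 1, tolerance = 0.02)
})

test_that("fit reports serialize to JSON", {
  m <- simulate_dual_probe(study_rates(bp = 1), noise_percent = 0, seed = 3)
  j <- bp_fit_json(fit_dual_probe(m, "ratio"))
  parsed <- jsonlite::fromJSON(j)
  expect_equal(parsed$estimator, "Ratio")
  expect_true(is.numeric(parsed$bp))
})
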