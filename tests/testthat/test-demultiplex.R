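# DCLS spectral unmixing and calibration on synthetic fingerprints.

make_library <- function(channels = default_channels()) {
  reference_library(
    list(S420 = synth_reference(list(c(900, 12, 1), c(1350, 8, 0.7)),
                                channels),
         S440 = synth_reference(list(c(1100, 12, 1), c(1600, 8, 0.9)),
                                channels)),
    background = synth_reference(list(c(1200, 400, 0.25)), channels))
}

test_that("synthetic references render Lorentzian peaks deterministically", {
  ch <- default_channels()
  s <- synth_reference(list(c(ch[200], 10, 2)), ch)   # on-grid center
  expect_equal(which.max(s$intensities), 200L)
  expect_equal(max(s$intensities), 2, tolerance = 1e-12)

  s0 <- synth_reference(list(), ch)
  expect_true(all(s0$intensities == 0))

  expect_warning(synth_reference(list(c(10, 5, 1)), ch), "outside")
  expect_error(synth_reference(list(c(1200, -1, 1)), ch), "width")

  # disjoint peak sets are spectrally near-orthogonal
  lib <- make_library(ch)
  a <- lib$flavor_spectra$S420$intensities
  b <- lib$flavor_spectra$S440$intensities
  cosine <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_lt(cosine, 0.1)
})

test_that("library construction enforces grid and conditioning", {
  ch <- default_channels()
  s <- synth_reference(list(c(900, 12, 1)), ch)
  expect_error(reference_library(
    list(a = s, b = synth_reference(list(c(900, 12, 1)),
                                    default_channels(200))),
    background = synth_reference(list(), ch)), "grid")
  expect_error(reference_library(
    list(a = s, b = raman_spectrum(ch, s$intensities * 2)),
    background = synth_reference(list(), ch)), "collinear")
})

test_that("unmixing recovers pure components and constructed mixtures", {
  lib <- make_library()
  ch <- lib$channels
  pure <- raman_spectrum(ch, lib$flavor_spectra$S420$intensities)
  u <- dcls_unmix(pure, lib)
  expect_equal(unname(u$weights), c(1, 0), tolerance = 1e-8)
  expect_lt(u$residual_norm, 1e-10)

  mix <- raman_spectrum(ch, 2 * lib$flavor_spectra$S420$intensities +
                            0.5 * lib$flavor_spectra$S440$intensities +
                            lib$background$intensities)
  for (nn in c(TRUE, FALSE)) {
    u2 <- dcls_unmix(mix, lib, nonneg = nn)
    expect_equal(unname(u2$weights), c(2, 0.5), tolerance = 1e-8)
    expect_equal(u2$background_weight, 1, tolerance = 1e-8)
  }

  zero <- raman_spectrum(ch, numeric(length(ch)))
  expect_equal(unname(dcls_unmix(zero, lib)$weights), c(0, 0))

  expect_error(dcls_unmix(raman_spectrum(default_channels(100),
                                         numeric(100)), lib), "grid")
})

test_that("background subtraction mode matches co-fitting on clean data", {
  lib <- make_library()
  mix <- raman_spectrum(lib$channels,
                        1.5 * lib$flavor_spectra$S420$intensities +
                        0.25 * lib$flavor_spectra$S440$intensities +
                        lib$background$intensities)
  u <- dcls_unmix(mix, lib, background = "subtract")
  expect_equal(unname(u$weights), c(1.5, 0.25), tolerance = 1e-8)
  expect_true(is.na(u$background_weight))
})

test_that("calibration converts weights to concentrations linearly", {
  sw <- c(S420 = 0.8, S440 = 1.2)
  expect_equal(calibrate(sw, sw), c(S420 = 150, S440 = 150))
  expect_equal(unname(calibrate(c(S420 = 0, S440 = 0), sw)), c(0, 0))
  expect_equal(calibrate(sw / 2, sw), c(S420 = 75, S440 = 75))
  expect_error(calibrate(sw, c(S420 = 0, S440 = 1)), "calibration")
})

test_that("estimated concentration is linear in truth from 1 to 400 pM", {
  lib <- make_library()
  stock_c <- 150
  stock <- raman_spectrum(lib$channels,
                          lib$flavor_spectra$S420$intensities +
                          lib$flavor_spectra$S440$intensities +
                          lib$background$intensities)
  sw <- dcls_unmix(stock, lib)$weights
  truth <- c(1, 5, 20, 50, 100, 150, 250, 400)
  est <- vapply(truth, function(cc) {
    w <- cc / stock_c                    # weights scale with concentration
    m <- raman_spectrum(lib$channels,
                        w * lib$flavor_spectra$S420$intensities +
                        w * lib$flavor_spectra$S440$intensities +
                        lib$background$intensities)
    unname(calibrate(dcls_unmix(m, lib)$weights, sw)[1L])
  }, numeric(1))
  fit <- lm(est ~ truth)
  r2 <- 1 - sum(residuals(fit)^2) / sum((est - mean(est))^2)
  expect_gt(r2, 0.999)
})

test_that("unmixing weights are unbiased under additive spectral noise", {
  lib <- make_library()
  clean <- 1.2 * lib$flavor_spectra$S420$intensities +
           0.6 * lib$flavor_spectra$S440$intensities +
           lib$background$intensities
  sigma <- 0.01 * max(clean)
  set.seed(41)
  w <- t(vapply(1:300, function(i) {
    sp <- raman_spectrum(lib$channels, clean + rnorm(length(clean), 0, sigma))
    dcls_unmix(sp, lib)$weights
  }, numeric(2)))
  mc_err <- 3 * sigma                    # generous Monte-Carlo margin
  expect_lt(abs(mean(w[, 1]) - 1.2), mc_err)
  expect_lt(abs(mean(w[, 2]) - 0.6), mc_err)
})
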