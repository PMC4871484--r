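test_that("lambda-max refinement recovers band maxima off and on the grid", {
  wl <- seq(380, 700, by = 1)
  s <- spectrum(wl, extinction_at(spectral_band(524, 100, 50000), wl) * 1e-5)
  expect_equal(find_lambda_max(s), 524, tolerance = 0.1 / 524)
  # shifted off-grid maximum
  s2 <- spectrum(wl, extinction_at(spectral_band(524.4, 100, 50000), wl) * 1e-5)
  expect_lt(abs(find_lambda_max(s2) - 524.4), 0.1)
  # symmetric triangle peak exactly on a grid point
  tri <- spectrum(wl, pmax(0, 1 - abs(wl - 550) / 40))
  expect_equal(find_lambda_max(tri, window = 10), 550)
})

test_that("lambda-max of a two-Gaussian blend matches a bisection oracle", {
  b1 <- spectral_band(520, 90, 50000)
  b2 <- spectral_band(560, 110, 30000)
  f <- function(x) extinction_at(b1, x) + extinction_at(b2, x)
  dfdx <- function(x) (f(x + 1e-5) - f(x - 1e-5)) / 2e-5
  lo <- 520; hi <- 560
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (dfdx(mid) > 0) lo <- mid else hi <- mid
  }
  oracle <- (lo + hi) / 2
  wl <- seq(400, 680, by = 1)
  s <- spectrum(wl, f(wl))
  expect_lt(abs(find_lambda_max(s, window = 12) - oracle), 0.01)
})

test_that("edge maxima and thin windows are rejected", {
  wl <- seq(400, 500, by = 1)
  rising <- spectrum(wl, wl / 500)
  expect_error(find_lambda_max(rising), "edge")
  s <- spectrum(seq(400, 500, by = 20), c(0.1, 0.4, 1, 0.4, 0.1, 0.05))
  expect_error(find_lambda_max(s, window = 30), "5 points")
})

test_that("purity index is the interpolated 280 nm to peak absorbance ratio", {
  wl <- seq(250, 700, by = 1)
  a <- 0.65 * exp(-((wl - 280) / 30)^2) + 0.50 * exp(-((wl - 524) / 60)^2)
  s <- spectrum(wl, a)
  expect_equal(purity_index(s, 524), 0.65 / 0.50, tolerance = 1e-3)
  flat <- spectrum(wl, rep(0, length(wl)))
  expect_error(purity_index(flat, 524), "non-positive")
  eq <- spectrum(wl, exp(-((wl - 280) / 30)^2) + exp(-((wl - 524) / 60)^2) -
                   exp(-((280 - 524) / 60)^2))
  expect_equal(purity_index(eq, 280), 1, tolerance = 1e-6)
})

test_that("oxime-referenced extinction reproduces the generating coefficient", {
  # bands separated enough that tail contamination is below 1e-9
  # equal extrema return the oxime reference itself
  pair <- make_bleach_pair(spectral_band(524, 55, 33600),
                           spectral_band(360, 50, 33600))
  bd <- bleach_difference(pair$before, pair$after)
  expect_equal(compute_extinction(bd), 33600, tolerance = 1e-9)
  # a ratio of 2 doubles the reference
  pair2 <- make_bleach_pair(spectral_band(524, 55, 67200),
                            spectral_band(360, 50, 33600))
  expect_equal(compute_extinction(bleach_difference(pair2$before, pair2$after)),
               67200, tolerance = 1e-9)
  # identity for random band parameters with separated, on-grid band centers
  # (an off-grid center samples the extremum slightly below the peak)
  set.seed(21)
  for (i in 1:10) {
    eps_rh <- runif(1, 20000, 80000)
    eps_ox <- runif(1, 20000, 50000)
    pr <- make_bleach_pair(
      spectral_band(sample(510:560, 1), runif(1, 40, 55), eps_rh),
      spectral_band(sample(340:365, 1), runif(1, 40, 50), eps_ox),
      concentration = runif(1, 1e-6, 1e-4))
    bdi <- bleach_difference(pr$before, pr$after, oxime_epsilon = eps_ox)
    expect_equal(compute_extinction(bdi), eps_rh, tolerance = 1e-9)
  }
  # realistic wide bands: overlap limits the calibration to the tail level
  wide <- make_bleach_pair(spectral_band(524, 100, 50000),
                           spectral_band(360, 80, 33600))
  bdw <- bleach_difference(wide$before, wide$after)
  expect_equal(compute_extinction(bdw), 50000, tolerance = 1e-3)
})

test_that("noiseless double titration is recovered to high precision", {
  tt <- make_titration_dataset(pk_low = 3, pk_high = 10,
                               plateaus = c(535, 525, 517),
                               pH_grid = seq(1, 12, length.out = 40),
                               noise_sd = 0)
  fit <- fit_titration(tt)
  expect_equal(fit$pk_low, 3, tolerance = 1e-6)
  expect_equal(fit$pk_high, 10, tolerance = 1e-6)
  expect_equal(c(fit$plateau_acid, fit$plateau_mid, fit$plateau_base),
               c(535, 525, 517), tolerance = 1e-6)
  expect_lt(fit$fit_rms, 1e-7)
})

test_that("single-transition fits recover a standard Henderson-Hasselbalch midpoint", {
  pH <- seq(4, 10, length.out = 20)
  y <- 530 + (540 - 530) / (1 + 10^(pH - 7.2))
  fit <- fit_titration(data.frame(pH = pH, y = y), n_transitions = 1)
  expect_equal(fit$pk_low, 7.2, tolerance = 1e-6)
  expect_true(is.na(fit$pk_high))
})

test_that("pK estimates stay within 0.15 units under 0.3 nm noise", {
  errs <- sapply(1:20, function(s) {
    tt <- make_titration_dataset(noise_sd = 0.3, seed = s)
    fit <- suppressWarnings(fit_titration(tt))
    c(abs(fit$pk_low - 3), abs(fit$pk_high - 10))
  })
  expect_lt(stats::median(errs[1, ]), 0.15)
  expect_lt(stats::median(errs[2, ]), 0.15)
})

test_that("titration fitting is invariant to row order and constant shifts", {
  tt <- make_titration_dataset(noise_sd = 0.2, seed = 31)
  fit <- suppressWarnings(fit_titration(tt))
  perm <- sample(nrow(tt))
  fit_p <- suppressWarnings(fit_titration(tt[perm, ]))
  expect_equal(fit_p$pk_low, fit$pk_low, tolerance = 1e-6)
  expect_equal(fit_p$pk_high, fit$pk_high, tolerance = 1e-6)
  shifted <- tt
  shifted$lambda_max <- shifted$lambda_max + 40
  fit_s <- suppressWarnings(fit_titration(shifted))
  expect_equal(fit_s$pk_low, fit$pk_low, tolerance = 1e-5)
  expect_equal(fit_s$plateau_base, fit$plateau_base + 40, tolerance = 1e-4)
})

test_that("unfittable titration tables are rejected", {
  expect_error(fit_titration(data.frame(pH = 1:10, y = rep(520, 10))),
               "constant")
  expect_error(fit_titration(data.frame(pH = c(3, 7, 9), y = c(1, 2, 3))),
               "fewer data points")
})
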