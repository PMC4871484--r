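test_that("a noiseless single exponential is recovered essentially exactly", {
  times <- 10^seq(-5, -1, length.out = 80)
  red <- synth_exp_reduced(times, 1e-3, matrix(-1, 1, 1))
  fit <- fit_global(red, 1)
  expect_equal(fit$lifetimes, 1e-3, tolerance = 1e-6)
  expect_equal(unname(fit$das[1, 1]), -1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("noiseless multi-exponential data in the model class is recovered to 0.1%", {
  times <- 10^seq(-6, 0, length.out = 250)
  taus <- c(2e-5, 4e-4, 9e-3, 7e-2)           # ratios >= 5
  das <- matrix(c(-20, 12, 5, -8,
                  10, -6, 3, 4,
                  -5, 8, -2, 6) * 1e-3, nrow = 4)
  red <- synth_exp_reduced(times, taus, das)
  fit <- fit_global(red, 4)
  expect_equal(fit$lifetimes, taus, tolerance = 1e-3)
  expect_lt(sqrt(mean((fit$das - das)^2)) / sqrt(mean(das^2)), 5e-3)
})

test_that("two-exponential fit agrees with an exhaustive log-grid search oracle", {
  times <- 10^seq(-5, 0, length.out = 120)
  taus <- c(1e-3, 1e-2)
  das <- matrix(c(-1, 0.6, 0.5, -0.8), nrow = 2)
  red <- synth_exp_reduced(times, taus, das)
  Y <- t(red$delta_A)
  rss_at <- function(lt1, lt2) {
    X <- exp(-outer(times, 1 / exp(c(lt1, lt2))))
    sum((Y - X %*% qr.coef(qr(X), Y))^2)
  }
  grid <- seq(log(1e-4), log(1e-1), length.out = 61)
  cell <- diff(grid)[1]
  rss <- outer(grid, grid, Vectorize(rss_at))
  best <- arrayInd(which.min(rss), dim(rss))
  oracle <- sort(exp(grid[as.vector(best)]))
  fit <- fit_global(red, 2)
  expect_lt(max(abs(log(fit$lifetimes) - log(oracle))), cell)
})

test_that("lifetimes stay accurate under the experiment's noise level", {
  times <- 10^seq(-6, 0, length.out = 300)
  taus <- c(3.5e-6, 84e-6, 11e-3, 82e-3)
  das <- matrix(c(-30, 15, 8, -12,
                  20, -10, 5, 8,
                  -12, 9, -4, 10,
                  -25, 14, 7, -9,
                  18, -8, 6, 5) * 1e-3, nrow = 4)
  errs <- sapply(1:20, function(s) {
    red <- synth_exp_reduced(times, taus, das, noise_sd = 3e-4, seed = 300 + s)
    fit <- fit_global(red, 4)
    abs(fit$lifetimes / taus - 1)
  })
  expect_true(all(apply(errs, 1, stats::median) < 0.05))
})

test_that("wavelength permutation permutes DAS columns; scaling scales DAS", {
  times <- 10^seq(-5, 0, length.out = 100)
  taus <- c(5e-4, 2e-2)
  das <- matrix(c(-1, 0.5, 0.8, -0.3, 0.2, 0.9), nrow = 2)
  red <- synth_exp_reduced(times, taus, das)
  fit <- fit_global(red, 2)
  perm <- c(3, 1, 2)
  redp <- red
  redp$delta_A <- red$delta_A[perm, ]
  redp$wavelengths <- red$wavelengths[perm]
  fitp <- fit_global(redp, 2)
  expect_equal(fitp$lifetimes, fit$lifetimes, tolerance = 1e-8)
  expect_equal(unname(fitp$das), unname(fit$das[, perm]), tolerance = 1e-6)
  redc <- red
  redc$delta_A <- 3.7 * red$delta_A
  fitc <- fit_global(redc, 2)
  expect_equal(fitc$lifetimes, fit$lifetimes, tolerance = 1e-8)
  expect_equal(unname(fitc$das), unname(3.7 * fit$das), tolerance = 1e-6)
})

test_that("initial amplitude reconstruction sums the DAS at one wavelength", {
  times <- 10^seq(-5, -1, length.out = 60)
  red <- synth_exp_reduced(times, c(1e-3, 1e-2),
                           matrix(c(0.5, -0.5, -1, 0.25), nrow = 2))
  fit <- fit_global(red, 2)
  expect_equal(reconstruct_initial_amplitude(fit, 1), 0, tolerance = 1e-6)
  expect_equal(reconstruct_initial_amplitude(fit, 2), -0.75, tolerance = 1e-6)
  expect_error(reconstruct_initial_amplitude(fit, 999), "not among")
})

test_that("initial amplitude matches the generator's flash-time transient", {
  sch <- small_chain_scheme()
  wl <- c(480, 560)
  acq <- quick_acq(n = 2048, noise_sd = 0, wl = wl)
  ds <- make_photocycle_dataset(sch, acq)
  red <- merge_traces(reduce_log_blocks(ds$fast), reduce_log_blocks(ds$slow))
  fit <- fit_global(red, 3)
  d0 <- photocyclr:::model_delta_A(sch, wl, 1e-12)
  expect_equal(reconstruct_initial_amplitude(fit, 560), d0[2, 1],
               tolerance = 1e-3)
})

test_that("component count selection stops when extra exponentials stop paying", {
  times <- 10^seq(-5, -1, length.out = 100)
  pure <- synth_exp_reduced(times, 1e-3, matrix(c(-1, 0.5), 1, 2))
  sel <- select_n_exponentials(pure, 3)
  expect_identical(sel$n_selected, 1L)
  expect_identical(nrow(sel$report), 3L)

  noise <- synth_exp_reduced(times, 1e-3, matrix(0, 1, 3),
                             noise_sd = 3e-4, seed = 8)
  seln <- select_n_exponentials(noise, 3)
  expect_identical(seln$n_selected, 1L)
  expect_lt(max(abs(seln$fits[[1]]$das)), 3 * 3e-4)
})

test_that("degenerate requests are rejected", {
  times <- 10^seq(-4, -2, length.out = 5)
  red <- synth_exp_reduced(times, 1e-3, matrix(1, 1, 1))
  expect_error(fit_global(red, 5), "time points")
  expect_error(fit_global(red, 0), "n_exponentials")
  expect_error(fit_global(red, 2, init = c(1e-3, -1)), "> 0")
})

test_that("block weighting uses the reduction provenance", {
  ts <- raw_trace(matrix(exp(-(1:600) * 1e-6 / 2e-4), nrow = 1))
  red <- reduce_log_blocks(ts)
  fit_w <- fit_global(red, 1, weighting = "block")
  expect_equal(fit_w$lifetimes, 2e-4, tolerance = 1e-3)
  red$provenance$block_sizes <- NULL
  expect_error(fit_global(red, 1, weighting = "block"), "provenance")
})
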