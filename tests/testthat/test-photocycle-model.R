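test_that("scheme construction enforces mass conservation and valid inputs", {
  b <- spectral_band(500, 100, 1000)
  K <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(c("G", "A"), c("G", "A")))
  sch <- photocycle_scheme(list(G = b, A = b), K, c(G = 0, A = 1), "G")
  expect_equal(colSums(sch$rate_matrix), c(G = 0, A = 0))
  expect_error(photocycle_scheme(list(G = b, A = b), -K, c(G = 0, A = 1), "G"),
               "non-negative")
  expect_error(photocycle_scheme(list(G = b, A = b), K, c(G = 0.5, A = 0.4),
                                 "G"), "sum to 1")
  expect_error(photocycle_scheme(list(G = b, A = b), K, c(G = 0, A = 1), "Z"),
               "ground")
})

test_that("populations conserve mass, stay in [0,1], and solve trivial cases", {
  sch <- e17r_scheme()
  times <- 10^seq(-7, 0, length.out = 200)
  tr <- simulate_populations(sch, times)
  expect_lt(max(abs(colSums(tr$populations) - 1)), 1e-10)
  expect_true(all(tr$populations >= -1e-12 & tr$populations <= 1 + 1e-12))
  # a state with no decay keeps its population
  b <- spectral_band(500, 100, 1000)
  K <- matrix(0, 2, 2, dimnames = list(c("G", "A"), c("G", "A")))
  frozen <- photocycle_scheme(list(G = b, A = b), K, c(G = 0, A = 1), "G")
  tr2 <- simulate_populations(frozen, c(0, 1, 100))
  expect_equal(tr2$populations["A", ], rep(1, 3))
})

test_that("A->B->C with matched rates follows the k t exp(-kt) law", {
  b <- spectral_band(500, 100, 1000)
  k <- 1000
  # exactly matched rates are defective; approach the limit numerically
  K <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  K["B", "A"] <- k
  K["C", "B"] <- k * (1 + 1e-7)
  sch <- photocycle_scheme(list(A = b, B = b, C = b), K,
                           c(A = 1, B = 0, C = 0), ground = "C")
  times <- seq(1e-5, 5e-3, length.out = 50)
  tr <- simulate_populations(sch, times)
  expect_equal(tr$populations["B", ], k * times * exp(-k * times),
               tolerance = 1e-4)
  # and the analytic occupancy law peaks at 1/e at t = 1/k
  expect_equal(max_transient_occupancy(k, k), exp(-1), tolerance = 1e-12)
})

test_that("eigen populations agree with an adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  sch <- e17r_scheme()
  times <- c(0, 10^seq(-7, 0, length.out = 60))
  ana <- simulate_populations(sch, times)$populations
  K <- sch$rate_matrix
  ode <- deSolve::lsoda(y = sch$initial_populations,
                        times = times,
                        func = function(t, y, p) list(K %*% y),
                        rtol = 1e-11, atol = 1e-12)
  num <- t(ode[, -1])
  expect_lt(max(abs(ana - num)), 1e-8)
})

test_that("defective rate matrices are rejected with perturbation advice", {
  b <- spectral_band(500, 100, 1000)
  K <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  K["B", "A"] <- 100
  K["C", "B"] <- 100
  sch <- photocycle_scheme(list(A = b, B = b, C = b), K,
                           c(A = 1, B = 0, C = 0), ground = "C")
  expect_error(simulate_populations(sch, 1), "perturb")
  expect_error(predict_das(sch, c(500, 550)), "perturb|degenerate")
})

test_that("predicted DAS carries the scheme's lifetimes and amplitudes", {
  # one intermediate: single DAS value = delta-extinction x initial population
  g <- spectral_band(524, 100, 50000)
  a <- spectral_band(560, 100, 40000)
  K <- matrix(0, 2, 2, dimnames = list(c("G", "A"), c("G", "A")))
  K["G", "A"] <- 1 / 5e-3
  sch <- photocycle_scheme(list(G = g, A = a), K, c(G = 0, A = 1), "G",
                           excited_fraction = 0.2, concentration = 1e-5)
  pd <- predict_das(sch, 524)
  expect_equal(pd$lifetimes, 5e-3)
  de <- extinction_at(a, 524) - extinction_at(g, 524)
  expect_equal(pd$das[1, 1], de * 1e-5 * 0.2, tolerance = 1e-12)

  # default scheme: the four printed lifetimes by construction
  pd4 <- predict_das(e17r_scheme(), c(400, 500, 600))
  expect_equal(pd4$lifetimes, E17R_LIFETIMES, tolerance = 1e-12)
  expect_identical(dim(pd4$das), c(4L, 3L))
})

test_that("predict_das round-trips through simulation and global fitting", {
  sch <- small_chain_scheme()
  wl <- c(420, 480, 530, 580, 630)
  pd <- predict_das(sch, wl)
  times <- 10^seq(log10(2e-6), log10(0.6), length.out = 300)
  D <- photocyclr:::model_delta_A(sch, wl, times)
  red <- structure(list(times = times, delta_A = D, wavelengths = wl,
                        provenance = list(block_sizes = rep(1L, length(times)))),
                   class = "reduced_trace_set")
  fit <- fit_global(red, 3)
  expect_equal(fit$lifetimes, pd$lifetimes, tolerance = 1e-3)
  expect_lt(sqrt(mean((fit$das - pd$das)^2)) / sqrt(mean(pd$das^2)), 5e-3)
})

test_that("peak transient occupancy matches its closed form and the simulated peak", {
  expect_equal(max_transient_occupancy(1e6, 1), 1, tolerance = 1e-4)
  expect_equal(max_transient_occupancy(1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(max_transient_occupancy(1, 2), 0.25, tolerance = 1e-12)
  b <- spectral_band(500, 100, 1000)
  # the exactly matched ratio 10^0 is the defective limit, checked analytically
  for (lr in setdiff(seq(-3, 3, by = 0.5), 0)) {
    k1 <- 10^lr
    k2 <- 1
    K <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    K["B", "A"] <- k1
    K["C", "B"] <- k2
    sch <- photocycle_scheme(list(A = b, B = b, C = b), K,
                             c(A = 1, B = 0, C = 0), ground = "C")
    popB <- function(t) simulate_populations(sch, t)$populations["B", ]
    t_peak <- log(k1 / k2) / (k1 - k2)
    peak <- stats::optimize(popB, c(t_peak / 50, t_peak * 50),
                            maximum = TRUE, tol = 1e-12)$objective
    expect_equal(max_transient_occupancy(k1, k2), unname(peak),
                 tolerance = 1e-6)
  }
})

test_that("blue-light shunt reduces the photostationary pump current", {
  sch <- e17r_scheme(include_m = TRUE)
  expect_equal(steady_state_current(sch, green_rate = 5, blue_rate = 0,
                                    shunt_branch_ratio = 1), 1)
  cur <- vapply(c(0, 1, 10, 100, 1000), function(b)
    steady_state_current(sch, green_rate = 5, blue_rate = b,
                         shunt_branch_ratio = 0.5), numeric(1))
  expect_lt(cur[2], 1)
  expect_true(all(diff(cur) < 0))   # monotone decrease with blue intensity
  expect_error(steady_state_current(sch, green_rate = 0, blue_rate = 1,
                                    shunt_branch_ratio = 1), "excitation")
})

test_that("two-state toy pump matches the hand-derived photostationary flux", {
  # G --g--> E --k--> G (pumping), shunt E --b r--> G:
  # relative current = (g + k) / (g + k + b r)
  b <- spectral_band(500, 100, 1000)
  k <- 50
  K <- matrix(0, 2, 2, dimnames = list(c("G", "E"), c("G", "E")))
  K["G", "E"] <- k
  sch <- photocycle_scheme(list(G = b, E = b), K, c(G = 0, E = 1), "G")
  for (g in c(1, 20)) for (br in c(0.3, 7)) {
    expect_equal(steady_state_current(sch, g, br, 1, shunt_state = "E"),
                 (g + k) / (g + k + br), tolerance = 1e-10)
  }
})

test_that("explicit M variant keeps near-matched formation and decay", {
  sch <- e17r_scheme(include_m = TRUE)
  expect_true("M" %in% names(sch$states))
  lt <- photocycle_lifetimes(sch)
  expect_identical(length(lt), 5L)
  times <- 10^seq(-7, 0, length.out = 400)
  tr <- simulate_populations(sch, times)
  peakM <- max(tr$populations["M", ])
  expect_equal(peakM, exp(-1), tolerance = 0.05)  # near the matched-rate limit
  expect_error(e17r_scheme(include_m = TRUE, m_rate_split = 0), "defective")
})
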