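# Shared fixtures and independent oracles, all built in code.

E17R_LIFETIMES <- c(3.5e-6, 84e-6, 11e-3, 82e-3)

# Build a reduced trace set directly from an exponential-sum model:
# das is an n_exp x n_wavelengths amplitude matrix.
synth_exp_reduced <- function(times, taus, das, noise_sd = 0, seed = NULL) {
  X <- exp(-outer(times, 1 / taus))          # times x n_exp
  D <- t(X %*% das)                          # wavelengths x times
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    D <- D + matrix(rnorm(length(D), sd = noise_sd), nrow = nrow(D))
  }
  structure(list(times = times, delta_A = D,
                 wavelengths = seq_len(nrow(D)),
                 provenance = list(block_sizes = rep(1L, length(times)))),
            class = "reduced_trace_set")
}

# Uniform raw trace set with given values (wavelengths x samples).
raw_trace <- function(values, dt = 1e-6, wavelengths = seq_len(nrow(values))) {
  photocyclr:::trace_set(dt * seq_len(ncol(values)), values, wavelengths)
}

# Independent brute-force enumerator of the logarithmic reduction: walks the
# raw samples block by block, doubling the block size after every
# points-per-century blocks, discarding an incomplete tail block.
brute_reduce <- function(x, ppc = 100) {
  n <- length(x)
  out <- numeric(0)
  pos <- 1L
  century <- 1L
  repeat {
    bs <- 2L^(century - 1L)
    emitted <- 0L
    while (emitted < ppc && pos + bs - 1L <= n) {
      out <- c(out, mean(x[pos:(pos + bs - 1L)]))
      pos <- pos + bs
      emitted <- emitted + 1L
    }
    if (emitted < ppc) break
    century <- century + 1L
  }
  out
}

brute_reduce_count <- function(n, ppc = 100) {
  cnt <- 0L
  pos <- 1L
  century <- 1L
  repeat {
    bs <- 2L^(century - 1L)
    emitted <- 0L
    while (emitted < ppc && pos + bs - 1L <= n) {
      cnt <- cnt + 1L
      pos <- pos + bs
      emitted <- emitted + 1L
    }
    if (emitted < ppc) break
    century <- century + 1L
  }
  cnt
}

# A small three-state chain scheme with well-separated lifetimes and distinct
# bands, cheap enough for round-trip fitting tests.
small_chain_scheme <- function(lifetimes = c(1e-5, 1e-3, 5e-2)) {
  bands <- list(G = spectral_band(524, 100, 50000),
                A = spectral_band(565, 95, 42000),
                B = spectral_band(480, 110, 38000),
                C = spectral_band(610, 120, 46000))
  k <- 1 / lifetimes
  K <- matrix(0, 4, 4, dimnames = list(names(bands), names(bands)))
  K["B", "A"] <- k[1]
  K["C", "B"] <- k[2]
  K["G", "C"] <- k[3]
  photocycle_scheme(bands, K, c(G = 0, A = 1, B = 0, C = 0), ground = "G",
                    excited_fraction = 0.15, concentration = 1e-5)
}

# Fast acquisition for unit tests (full-size acquisition is exercised in the
# acceptance suite).
quick_acq <- function(n = 2048, noise_sd = 0, seed = 1L,
                      fast_dt = 2e-6, slow_dt = 6e-4,
                      wl = c(400, 460, 520, 560, 620)) {
  default_acquisition(probe_wavelengths = wl, fast_dt = fast_dt,
                      slow_dt = slow_dt, n_samples_per_scope = n,
                      noise_sd = noise_sd, seed = seed)
}
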