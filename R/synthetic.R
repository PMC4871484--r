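# Run code with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Default E17R photocycle scheme
#'
#' The green-absorbing proteorhodopsin E17R photocycle as deduced from global
#' fitting of flash-photolysis data: a ground state absorbing at 524 nm and a
#' linear chain of red-shifted intermediates whose sequential decays carry the
#' four observed lifetimes 3.5 us, 84 us, 11 ms and 82 ms, the last being the
#' recovery of the dark state. The first intermediate is populated already at
#' the first sample (its formation lies below the instrumental time
#' resolution), which the scheme expresses by placing the t = 0+ population
#' entirely on the first intermediate.
#'
#' The default is the pure four-mode chain, since four exponentials is what the
#' data show. `include_m = TRUE` inserts an explicit M-like state (400 nm,
#' deprotonated Schiff base) after the 84 us step, with formation and decay
#' rates matched to within `m_rate_split`: near-matched formation and decay
#' keep its peak occupancy near 1/e while its band sits far from the strong
#' visible difference bands, which is why the state escapes detection in
#' transient spectra. An exact match would make the rate matrix defective
#' (non-diagonalizable), so a small split is kept; see
#' [max_transient_occupancy()] for the exactly-matched analytic limit.
#'
#' @param include_m insert the explicit M state (default `FALSE`).
#' @param m_rate_split relative excess of the M decay rate over its formation
#'   rate (default 0.05); must be positive when `include_m = TRUE`.
#' @param lifetimes the four chain lifetimes in seconds.
#' @param excited_fraction fraction of molecules cycling per flash.
#' @param concentration sample concentration in M (default gives a ground-state
#'   absorbance of 0.5 OD at 524 nm over a 1 cm path).
#' @param pathlength optical pathlength in cm.
#' @return a [photocycle_scheme()].
#' @export
e17r_scheme <- function(include_m = FALSE, m_rate_split = 0.05,
                        lifetimes = c(3.5e-6, 84e-6, 11e-3, 82e-3),
                        excited_fraction = 0.15,
                        concentration = 1e-5, pathlength = 1) {
  stopifnot(length(lifetimes) == 4L, all(lifetimes > 0),
            all(diff(lifetimes) > 0))
  # adjacent intermediates carry distinct bands so that every kinetic
  # component has a decay-associated spectrum of the order of 10 mOD
  bands <- list(
    G  = spectral_band(524, 100, 50000),
    P1 = spectral_band(560, 100, 45000),
    P2 = spectral_band(545, 105, 42000),
    P3 = spectral_band(590, 110, 45000),
    P4 = spectral_band(600, 120, 45000)
  )
  k <- 1 / lifetimes
  chain <- c("P1", "P2", "P3", "P4", "G")
  if (include_m) {
    if (m_rate_split <= 0)
      stop("m_rate_split must be > 0: exactly matched M formation and decay ",
           "rates give a defective rate matrix")
    bands$M <- spectral_band(400, 90, 30000)
    chain <- c("P1", "P2", "M", "P3", "P4", "G")
    k <- c(k[1], k[2], k[2] * (1 + m_rate_split), k[3], k[4])
  }
  bands <- bands[c(setdiff(chain, "G"), "G")]
  n <- length(bands)
  K <- matrix(0, n, n, dimnames = list(names(bands), names(bands)))
  for (i in seq_along(k)) K[chain[i + 1], chain[i]] <- k[i]
  p0 <- setNames(numeric(n), names(bands))
  p0["P1"] <- 1
  photocycle_scheme(bands, K, p0, ground = "G",
                    excited_fraction = excited_fraction,
                    concentration = concentration, pathlength = pathlength)
}

#' Flash-photolysis acquisition configuration
#'
#' The acquisition geometry of the E17R flash-photolysis experiment: 14 probe
#' wavelengths between 380 and 645 nm, a 10 ns excitation flash at 503 nm, and
#' two oscilloscopes digitizing the same transient at 200 ns/point and
#' 20 us/point, 46080 samples each (the "45k" raw points read as 45 x 1024).
#' Time zero is the flash; the first sample falls one dwell time later.
#'
#' @param probe_wavelengths strictly increasing probe wavelengths in nm.
#' @param fast_dt,slow_dt oscilloscope dwell times in s/point; fast < slow.
#' @param n_samples_per_scope samples recorded by each oscilloscope.
#' @param flash_time flash time in s (time origin).
#' @param flash_wavelength excitation wavelength in nm.
#' @param fluence_mJ_cm2 excitation fluence range, mJ/cm^2 (metadata only).
#' @param noise_sd Gaussian measurement noise per raw sample, absorbance units.
#' @param seed integer seed making simulated noise reproducible.
#' @return an object of class `acquisition_config`.
#' @export
default_acquisition <- function(probe_wavelengths = c(380, 400, 420, 440, 460,
                                                      480, 500, 517, 540, 562,
                                                      580, 600, 620, 645),
                                fast_dt = 200e-9, slow_dt = 20e-6,
                                n_samples_per_scope = 46080,
                                flash_time = 0, flash_wavelength = 503,
                                fluence_mJ_cm2 = c(5, 10),
                                noise_sd = 3e-4, seed = 1L) {
  stopifnot(is.numeric(probe_wavelengths))
  if (length(probe_wavelengths) > 0 && any(diff(probe_wavelengths) <= 0))
    stop("probe wavelengths must be strictly increasing")
  if (!(fast_dt < slow_dt)) stop("fast_dt must be smaller than slow_dt")
  if (n_samples_per_scope <= 0) stop("n_samples_per_scope must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(probe_wavelengths = probe_wavelengths,
                 fast_dt = fast_dt, slow_dt = slow_dt,
                 n_samples_per_scope = as.integer(n_samples_per_scope),
                 flash_time = flash_time, flash_wavelength = flash_wavelength,
                 fluence_mJ_cm2 = fluence_mJ_cm2,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acquisition_config")
}

# Construct a trace_set container with dimension checks.
trace_set <- function(times, delta_A, wavelengths, meta = NULL) {
  delta_A <- as.matrix(delta_A)
  stopifnot(length(times) == ncol(delta_A),
            length(wavelengths) == nrow(delta_A))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  rownames(delta_A) <- as.character(wavelengths)
  structure(list(times = times, delta_A = delta_A,
                 wavelengths = wavelengths, meta = meta),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace set: %d wavelengths x %d samples, t in [%.3g, %.3g] s\n",
              nrow(x$delta_A), ncol(x$delta_A), min(x$times), max(x$times)))
  invisible(x)
}

# Noiseless transient absorbance, wavelengths x times.
model_delta_A <- function(scheme, wavelengths, times) {
  P <- simulate_populations(scheme, times)$populations
  de <- delta_extinction(scheme, wavelengths)      # states x nm
  scale <- scheme$concentration * scheme$pathlength * scheme$excited_fraction
  scale * crossprod(de, P)                         # nm x times
}

#' Simulate a dual-oscilloscope flash-photolysis dataset
#'
#' Generates the raw trace sets of both oscilloscopes from a photocycle scheme:
#' the transient absorbance change at probe wavelength lambda is
#' deltaA(lambda, t) = sum_s c_s(t) (eps_s(lambda) - eps_ground(lambda)) * c * l
#' * excited_fraction, sampled uniformly at `fast_dt` and `slow_dt` starting one
#' dwell time after the flash, with independent Gaussian noise of standard
#' deviation `noise_sd` added to every sample. The first intermediate is fully
#' populated at the first sample (sub-resolution formation). Output is
#' bit-reproducible for a given `acq$seed`.
#'
#' @param scheme a [photocycle_scheme()], e.g. [e17r_scheme()].
#' @param acq an [default_acquisition()] configuration.
#' @return list with elements `fast` and `slow`, each a `trace_set`.
#' @examples
#' acq <- default_acquisition(n_samples_per_scope = 512, seed = 7)
#' ds <- make_photocycle_dataset(e17r_scheme(), acq)
#' ds$fast
#' @export
make_photocycle_dataset <- function(scheme, acq) {
  stopifnot(inherits(scheme, "photocycle_scheme"),
            inherits(acq, "acquisition_config"))
  if (length(acq$probe_wavelengths) == 0)
    stop("probe wavelength list must be non-empty")
  if (sum(scheme$initial_populations[names(scheme$initial_populations) !=
                                       scheme$ground]) <= 0)
    stop("scheme has no excited state: initial population is entirely in ",
         "the ground state")
  one <- function(dt) {
    times <- dt * seq_len(acq$n_samples_per_scope)
    D <- model_delta_A(scheme, acq$probe_wavelengths, times)
    if (acq$noise_sd > 0)
      D <- D + matrix(rnorm(length(D), sd = acq$noise_sd), nrow = nrow(D))
    trace_set(times, D, acq$probe_wavelengths, meta = acq)
  }
  with_seed(acq$seed, {
    fast <- one(acq$fast_dt)
    slow <- one(acq$slow_dt)
    list(fast = fast, slow = slow)
  })
}

#' Double Henderson-Hasselbalch titration curve
#'
#' The absorption-maximum observable of a chromophore with two titratable
#' groups: lambda_max(pH) = plateau_base
#'   + (plateau_mid - plateau_base) / (1 + 10^(hill_high (pH - pK_high)))
#'   + (plateau_acid - plateau_mid) / (1 + 10^(hill_low (pH - pK_low))).
#' At pH << pK_low the curve sits at the acid plateau, between the two pKs at
#' the mid plateau, and at pH >> pK_high at the basic plateau.
#'
#' @param pH numeric vector of pH values.
#' @param pk_low,pk_high transition midpoints (acidic and basic pK).
#' @param plateaus numeric length-3: acid, mid and basic plateau values (nm).
#' @param hill optional length-2 Hill coefficients (low, high); default 1.
#' @return observable at each pH (nm).
#' @export
titration_curve <- function(pH, pk_low, pk_high, plateaus, hill = c(1, 1)) {
  stopifnot(length(plateaus) == 3L, length(hill) == 2L)
  plateaus[3] +
    (plateaus[2] - plateaus[3]) / (1 + 10^(hill[2] * (pH - pk_high))) +
    (plateaus[1] - plateaus[2]) / (1 + 10^(hill[1] * (pH - pk_low)))
}

#' Simulate a pH-titration series
#'
#' Generates an observed lambda_max(pH) table from the double
#' Henderson-Hasselbalch model with Gaussian noise, emulating the red shift of
#' a green proteorhodopsin's absorption maximum on acidification (counterion
#' protonation, acidic pK) and the smaller shift near the basic pK.
#'
#' @param pk_low,pk_high generating pK values; `pk_low < pk_high` required.
#'   Transitions closer than 0.5 pH units are flagged with a warning attribute.
#' @param plateaus length-3 numeric (acid, mid, base) in nm; must decrease,
#'   i.e. red shift on acidification.
#' @param pH_grid pH values at which lambda_max is observed.
#' @param noise_sd Gaussian noise on lambda_max, nm.
#' @param seed integer seed.
#' @return data.frame with columns `pH` and `lambda_max`; attribute
#'   `overlapping_pks` is TRUE when |pK_high - pK_low| < 0.5.
#' @examples
#' tt <- make_titration_dataset(seed = 3)
#' head(tt)
#' @export
make_titration_dataset <- function(pk_low = 3, pk_high = 10,
                                   plateaus = c(535, 525, 517),
                                   pH_grid = seq(2, 11, length.out = 25),
                                   noise_sd = 0.3, seed = 1L) {
  if (!(pk_low < pk_high)) stop("pk_low must be smaller than pk_high")
  if (any(diff(plateaus) >= 0))
    stop("plateaus must decrease (acid > mid > base): red shift on acidification")
  overlapping <- abs(pk_high - pk_low) < 0.5
  if (overlapping)
    warning("pK values closer than 0.5 pH units: transitions overlap strongly")
  y <- titration_curve(pH_grid, pk_low, pk_high, plateaus)
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(y), sd = noise_sd))
  out <- data.frame(pH = pH_grid, lambda_max = y)
  attr(out, "overlapping_pks") <- overlapping
  out
}

#' Simulate a hydroxylamine bleach spectrum pair
#'
#' Spectra of a rhodopsin sample before and after hydroxylamine bleach: before,
#' the retinal-protein band; after, the retinal oxime band. Both are scaled by
#' concentration x pathlength (Beer-Lambert). The pair feeds
#' [bleach_difference()] / [compute_extinction()] for oxime-referenced
#' extinction-coefficient determination.
#'
#' @param rhodopsin_band,oxime_band [spectral_band()] objects.
#' @param concentration chromophore concentration in M; > 0.
#' @param pathlength optical pathlength in cm; > 0.
#' @param wavelengths evaluation grid in nm.
#' @return list with `before` and `after`, each a [spectrum()].
#' @export
make_bleach_pair <- function(rhodopsin_band, oxime_band,
                             concentration = 1e-5, pathlength = 1,
                             wavelengths = seq(250, 700, by = 1)) {
  stopifnot(inherits(rhodopsin_band, "spectral_band"),
            inherits(oxime_band, "spectral_band"))
  if (concentration <= 0) stop("concentration must be > 0")
  if (pathlength <= 0) stop("pathlength must be > 0")
  cl <- concentration * pathlength
  list(before = spectrum(wavelengths, cl * extinction_at(rhodopsin_band, wavelengths)),
       after  = spectrum(wavelengths, cl * extinction_at(oxime_band, wavelengths)))
}
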