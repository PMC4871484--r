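#' Steady-state absorption spectrum
#'
#' @param wavelengths strictly increasing wavelengths in nm.
#' @param absorbance absorbance (OD) at each wavelength.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, absorbance) {
  stopifnot(is.numeric(wavelengths), is.numeric(absorbance),
            length(wavelengths) == length(absorbance))
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelengths = wavelengths, absorbance = absorbance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d points, %g-%g nm\n", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Refined absorption-maximum wavelength
#'
#' Locates the grid maximum of a spectrum and refines it by a local quadratic
#' fit over a window around the peak, returning a continuous wavelength. The
#' maximum must be interior (a maximum on the first or last grid point means no
#' peak was captured).
#'
#' @param s a [spectrum()].
#' @param window width (nm) of the refinement window centered on the grid
#'   maximum; at least 5 points must fall inside it.
#' @return refined peak wavelength in nm.
#' @examples
#' wl <- seq(400, 650, 1)
#' s <- spectrum(wl, exp(-((wl - 524) / 60)^2))
#' find_lambda_max(s)
#' @export
find_lambda_max <- function(s, window = 30) {
  stopifnot(inherits(s, "spectrum"))
  i <- which.max(s$absorbance)
  if (i == 1L || i == length(s$wavelengths))
    stop("absorbance maximum lies on the spectrum edge: no interior peak")
  sel <- abs(s$wavelengths - s$wavelengths[i]) <= window / 2
  if (sum(sel) < 5) stop("fewer than 5 points in the refinement window")
  vertex <- function(keep, center) {
    x <- s$wavelengths[keep] - center
    y <- s$absorbance[keep]
    cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
    if (!is.finite(cf[3]) || cf[3] >= 0) return(NA_real_)
    unname(center - cf[2] / (2 * cf[3]))
  }
  # first pass over the full window, second pass over the 5 points nearest the
  # first vertex: shrinking the window removes the cubic bias of a single wide
  # quadratic fit on asymmetric peaks
  peak <- vertex(which(sel), s$wavelengths[i])
  if (!is.na(peak) && abs(peak - s$wavelengths[i]) <= window / 2) {
    near <- order(abs(s$wavelengths - peak))[1:5]
    peak2 <- vertex(near, peak)
    if (!is.na(peak2) && abs(peak2 - peak) <= window / 2) peak <- peak2
  }
  # fall back to the grid point for flat or strongly asymmetric peaks
  if (is.na(peak) || abs(peak - s$wavelengths[i]) > window / 2)
    s$wavelengths[i] else peak
}

#' Protein-to-chromophore purity index
#'
#' The ratio A(280 nm) / A(peak), the standard purity factor of a retinal
#' protein preparation: values near 1 indicate one retinal per properly folded
#' protein with little non-absorbing contamination; scattering and impurities
#' raise it.
#'
#' @param s a [spectrum()] covering both 280 nm and the chromophore peak.
#' @param chromophore_peak chromophore band maximum in nm.
#' @return A280 / A(peak), dimensionless.
#' @export
purity_index <- function(s, chromophore_peak) {
  stopifnot(inherits(s, "spectrum"))
  rng <- range(s$wavelengths)
  if (280 < rng[1] || 280 > rng[2] ||
      chromophore_peak < rng[1] || chromophore_peak > rng[2])
    stop("both 280 nm and the chromophore peak must lie within the spectrum")
  a280 <- stats::approx(s$wavelengths, s$absorbance, xout = 280)$y
  apk <- stats::approx(s$wavelengths, s$absorbance, xout = chromophore_peak)$y
  if (apk <= 0) stop("non-positive absorbance at the chromophore peak")
  a280 / apk
}

#' Bleach difference spectrum and its extrema
#'
#' The difference (after - before) of a hydroxylamine bleach pair: bleaching
#' the rhodopsin gives a negative extremum at the chromophore band
#' (deltaA(Rh)) and a positive extremum at the retinal-oxime band
#' (deltaA(oxime)). With the known oxime extinction coefficient these two
#' amplitudes calibrate the rhodopsin extinction coefficient. The extrema are
#' read directly off the difference spectrum, as in the experimental
#' procedure; when the two bands overlap, each extremum is contaminated by the
#' other band's tail, so the calibration is exact only for spectrally
#' separated bands (for Gaussian bands the relative error is the tail
#' amplitude of one band at the other's maximum).
#'
#' @param before,after [spectrum()] objects on the same wavelength grid.
#' @param oxime_epsilon molar extinction of the retinal oxime at its band
#'   maximum, M^-1 cm^-1 (default 33600).
#' @return an object of class `bleach_difference` with the difference
#'   spectrum, `dA_rhodopsin`, `dA_oxime`, and `oxime_epsilon`.
#' @export
bleach_difference <- function(before, after, oxime_epsilon = 33600) {
  stopifnot(inherits(before, "spectrum"), inherits(after, "spectrum"))
  if (length(before$wavelengths) != length(after$wavelengths) ||
      any(before$wavelengths != after$wavelengths))
    stop("before and after spectra must share one wavelength grid")
  if (oxime_epsilon <= 0) stop("oxime_epsilon must be > 0")
  d <- after$absorbance - before$absorbance
  dA_ox <- max(d)
  dA_rh <- -min(d)
  if (dA_ox <= 0 || dA_rh <= 0)
    stop("difference spectrum lacks a positive oxime and a negative ",
         "rhodopsin extremum")
  structure(list(difference = spectrum(before$wavelengths, d),
                 dA_rhodopsin = dA_rh, dA_oxime = dA_ox,
                 oxime_epsilon = oxime_epsilon),
            class = "bleach_difference")
}

#' Oxime-referenced rhodopsin extinction coefficient
#'
#' eps(Rh) = eps(oxime) * deltaA(Rh) / deltaA(oxime): the bleached rhodopsin
#' and the oxime formed are equimolar, so the extinction ratio equals the
#' difference-amplitude ratio.
#'
#' @param bd a [bleach_difference()].
#' @return rhodopsin molar extinction coefficient, M^-1 cm^-1.
#' @examples
#' pair <- make_bleach_pair(spectral_band(524, 100, 50000),
#'                          spectral_band(360, 80, 33600))
#' compute_extinction(bleach_difference(pair$before, pair$after))
#' @export
compute_extinction <- function(bd) {
  stopifnot(inherits(bd, "bleach_difference"))
  if (bd$dA_oxime == 0) stop("zero oxime amplitude")
  bd$oxime_epsilon * bd$dA_rhodopsin / bd$dA_oxime
}

#' Fit a (double) Henderson-Hasselbalch titration curve
#'
#' Nonlinear least-squares fit of [titration_curve()] to an observed
#' lambda_max(pH) table (or any scalar observable vs pH, e.g. absorbance at a
#' fixed wavelength). With `n_transitions = 2` the parameters are the acidic
#' and basic transition midpoints — reported as `pk_low` (acidic, the pK2 of
#' counterion protonation) and `pk_high` (basic, pK1) — and three plateaus;
#' with `n_transitions = 1` a single midpoint and two plateaus. Hill
#' coefficients are fixed at 1 unless `free_hill = TRUE`.
#'
#' @param table data.frame whose first column is pH and second the observable.
#' @param n_transitions 1 or 2.
#' @param free_hill also fit Hill coefficients (default fixed at 1).
#' @return an object of class `titration_fit`: `pk_low`, `pk_high` (NA for a
#'   single transition), `plateau_acid`, `plateau_mid`, `plateau_base`,
#'   `hill`, `fit_rms`, `fitted`, `converged`. When the acid-side plateau is
#'   poorly constrained by the data (no observation below `pk_low`), a warning
#'   notes that it is an extrapolated parameter.
#' @examples
#' tt <- make_titration_dataset(seed = 5)
#' fit_titration(tt)
#' @export
fit_titration <- function(table, n_transitions = 2, free_hill = FALSE) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  pH <- table[[1]]
  y <- table[[2]]
  ok <- is.finite(pH) & is.finite(y)
  pH <- pH[ok]; y <- y[ok]
  if (!n_transitions %in% 1:2) stop("n_transitions must be 1 or 2")
  n_par <- if (n_transitions == 2) 5L else 3L
  if (free_hill) n_par <- n_par + n_transitions
  if (length(y) < n_par + 1)
    stop("fewer data points than fit parameters")
  if (stats::sd(y) == 0) stop("constant observable: nothing to fit")
  ylo <- stats::quantile(y, 0.05, names = FALSE)
  yhi <- stats::quantile(y, 0.95, names = FALSE)
  if (n_transitions == 2) {
    par0 <- c(pk_low = stats::quantile(pH, 1/3, names = FALSE),
              pk_high = stats::quantile(pH, 2/3, names = FALSE),
              acid = yhi, mid = stats::median(y), base = ylo,
              if (free_hill) c(h1 = 1, h2 = 1))
    model <- function(p)
      titration_curve(pH, p[1], p[2], p[3:5],
                      hill = if (free_hill) p[6:7] else c(1, 1))
  } else {
    par0 <- c(pk = stats::median(pH), acid = yhi, base = ylo,
              if (free_hill) c(h1 = 1))
    model <- function(p)
      p[3] + (p[2] - p[3]) / (1 + 10^((if (free_hill) p[4] else 1) * (pH - p[1])))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  if (n_transitions == 2 && p[1] > p[2]) {
    # relabel so pk_low is the acidic transition
    p[1:2] <- p[2:1]
    warning("fitted transitions came out reversed; midpoints relabeled ",
            "so that pk_low < pk_high")
  }
  if (n_transitions == 2 && min(pH) > p[1])
    warning("no data below the acidic midpoint: the acid plateau is an ",
            "extrapolated parameter (wide bounds)")
  res <- y - model(fit$par)
  structure(list(pk_low = unname(p[1]),
                 pk_high = if (n_transitions == 2) unname(p[2]) else NA_real_,
                 plateau_acid = unname(if (n_transitions == 2) p[3] else p[2]),
                 plateau_mid = if (n_transitions == 2) unname(p[4]) else NA_real_,
                 plateau_base = unname(if (n_transitions == 2) p[5] else p[3]),
                 hill = if (free_hill) unname(p[(n_par - n_transitions + 1):n_par])
                        else rep(1, n_transitions),
                 fit_rms = sqrt(mean(res^2)),
                 fitted = model(fit$par),
                 converged = fit$info %in% 1:4),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  if (is.na(x$pk_high))
    cat(sprintf("titration fit: pK = %.3f, plateaus %.2f -> %.2f, rms %.3g\n",
                x$pk_low, x$plateau_acid, x$plateau_base, x$fit_rms))
  else
    cat(sprintf(paste0("titration fit: pK2 (acidic) = %.3f, pK1 (basic) = %.3f\n",
                       "plateaus %.2f / %.2f / %.2f (acid/mid/base), rms %.3g\n"),
                x$pk_low, x$pk_high, x$plateau_acid, x$plateau_mid,
                x$plateau_base, x$fit_rms))
  invisible(x)
}
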