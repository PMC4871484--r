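#' First-order photocycle kinetic scheme
#'
#' A photocycle is represented as a set of named states (the dark/ground state
#' plus photo-intermediates), each carrying a [spectral_band()], together with a
#' first-order rate matrix K. Column j of K holds the rates out of state j:
#' `K[i, j]` (i != j) is the rate constant (s^-1) for the transition j -> i, and
#' each diagonal element is minus its column's off-diagonal sum, so that
#' populations obey dc/dt = K c with exact mass conservation.
#'
#' `initial_populations` describes the cycle entry at t = 0+, i.e. immediately
#' after the (sub-resolution) excitation flash, normalized within the excited
#' sub-ensemble: in the usual case the first intermediate carries population 1.
#' The fraction of molecules actually cycling, and the sample optical geometry,
#' are sample-level fields (`excited_fraction`, `concentration`, `pathlength`)
#' used when converting populations to absorbance changes.
#'
#' @param states named list of [spectral_band()] objects; names are state names.
#' @param rate_matrix square matrix of first-order rate constants (s^-1) with
#'   dimnames matching `states`; off-diagonals non-negative, columns summing to
#'   zero. If the diagonal is left as `NA` it is filled in automatically.
#' @param initial_populations named numeric vector over states, summing to 1.
#' @param ground name of the ground (dark) state; exactly one state.
#' @param excited_fraction fraction of the sample cycling after the flash.
#' @param concentration sample concentration in M.
#' @param pathlength optical pathlength in cm.
#' @return an object of class `photocycle_scheme`.
#' @seealso [e17r_scheme()], [simulate_populations()], [predict_das()]
#' @export
photocycle_scheme <- function(states, rate_matrix, initial_populations, ground,
                              excited_fraction = 1, concentration = 1,
                              pathlength = 1) {
  stopifnot(is.list(states), length(states) >= 1L)
  nm <- names(states)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("states must be a uniquely named list")
  for (s in states)
    if (!inherits(s, "spectral_band")) stop("every state needs a spectral_band")
  K <- as.matrix(rate_matrix)
  if (nrow(K) != length(states) || ncol(K) != length(states))
    stop("rate_matrix must be square with one row/column per state")
  if (is.null(dimnames(K))) dimnames(K) <- list(nm, nm)
  K <- K[nm, nm, drop = FALSE]
  diag(K) <- 0
  if (any(K < 0)) stop("off-diagonal rate constants must be non-negative")
  diag(K) <- -colSums(K)
  p0 <- initial_populations[nm]
  if (any(is.na(p0))) stop("initial_populations must name every state")
  if (any(p0 < 0)) stop("initial populations must be non-negative")
  if (abs(sum(p0) - 1) > 1e-9) stop("initial populations must sum to 1")
  if (length(ground) != 1L || !ground %in% nm)
    stop("exactly one ground state must be named and present in states")
  if (excited_fraction <= 0 || excited_fraction > 1)
    stop("excited_fraction must lie in (0, 1]")
  if (concentration <= 0) stop("concentration must be > 0")
  if (pathlength <= 0) stop("pathlength must be > 0")
  structure(list(states = states, rate_matrix = K,
                 initial_populations = p0, ground = ground,
                 excited_fraction = excited_fraction,
                 concentration = concentration, pathlength = pathlength),
            class = "photocycle_scheme")
}

#' @export
print.photocycle_scheme <- function(x, ...) {
  cat(sprintf("photocycle scheme: %d states (ground: %s)\n",
              length(x$states), x$ground))
  lt <- tryCatch(photocycle_lifetimes(x), error = function(e) NULL)
  if (!is.null(lt))
    cat("kinetic lifetimes:", paste(signif(lt, 4), collapse = ", "), "s\n")
  invisible(x)
}

#' Kinetic lifetimes of a scheme
#'
#' The lifetimes -1/lambda of the non-zero eigenvalues of the rate matrix,
#' ascending. These are the observable exponential time constants of any
#' transient following first-order kinetics on this scheme.
#'
#' @param scheme a [photocycle_scheme()].
#' @return numeric vector of lifetimes in seconds, ascending.
#' @export
photocycle_lifetimes <- function(scheme) {
  ed <- scheme_eigen(scheme)
  sort(-1 / ed$values[ed$kinetic])
}

# Eigen-decomposition of the rate matrix with validity checks shared by
# simulate_populations() and predict_das(). Rate matrices of branched schemes
# can in principle have complex eigenpairs; populations are real, so complex
# arithmetic is carried through and the real part taken at the end.
scheme_eigen <- function(scheme) {
  K <- scheme$rate_matrix
  ed <- eigen(K)
  V <- ed$vectors
  if (rcond(V) < 1e-12)
    stop("rate matrix is defective (repeated eigenvalue without a full ",
         "eigenspace); perturb nearly-equal rate constants slightly")
  scale <- max(abs(ed$values), 1e-300)
  kinetic <- Mod(ed$values) > 1e-9 * scale
  if (any(Im(ed$values[kinetic]) != 0) &&
      max(abs(Im(ed$values))) < 1e-9 * scale) {
    ed$values <- Re(ed$values)
    V <- Re(V)
  }
  list(values = ed$values, vectors = V, Vinv = solve(V), kinetic = kinetic)
}

#' Analytic population dynamics of a photocycle
#'
#' Solves dc/dt = K c exactly by eigen-decomposition of the rate matrix: no
#' step-size error, any time grid. Defective (non-diagonalizable) rate matrices
#' are rejected with advice to perturb the offending rates.
#'
#' @param scheme a [photocycle_scheme()].
#' @param times numeric vector of times in seconds, all >= 0.
#' @return an object of class `population_trajectory`: list with `times` and
#'   `populations`, a states x times matrix of fractional populations.
#' @examples
#' sch <- e17r_scheme()
#' tr <- simulate_populations(sch, 10^seq(-7, 0, length.out = 50))
#' colSums(tr$populations)[1:3]  # mass conservation
#' @export
simulate_populations <- function(scheme, times) {
  stopifnot(inherits(scheme, "photocycle_scheme"), is.numeric(times))
  if (any(times < 0)) stop("times must be >= 0")
  ed <- scheme_eigen(scheme)
  w <- ed$Vinv %*% scheme$initial_populations
  E <- exp(outer(ed$values, times))          # modes x times
  P <- Re(ed$vectors %*% (E * as.vector(w)))
  dimnames(P) <- list(names(scheme$states), NULL)
  structure(list(times = times, populations = P),
            class = "population_trajectory")
}

# Difference extinction of every state against the ground state, states x nm.
delta_extinction <- function(scheme, wavelengths) {
  eg <- extinction_at(scheme$states[[scheme$ground]], wavelengths)
  de <- vapply(scheme$states,
               function(b) extinction_at(b, wavelengths) - eg,
               numeric(length(wavelengths)))
  t(matrix(de, nrow = length(wavelengths),
           dimnames = list(NULL, names(scheme$states))))
}

#' Predicted lifetimes and decay-associated spectra of a scheme
#'
#' The forward counterpart of the global fit: for a first-order scheme the
#' transient absorbance is exactly a sum of exponentials whose lifetimes are
#' -1/eigenvalue of the rate matrix and whose wavelength-dependent amplitudes
#' (the decay-associated spectra, DAS) are the kinetic eigenmode loadings
#' weighted by the states' difference extinctions. On noiseless simulated data
#' this round-trips with [fit_global()].
#'
#' @param scheme a [photocycle_scheme()].
#' @param wavelengths probe wavelengths in nm.
#' @return list with `lifetimes` (seconds, ascending) and `das`
#'   (n_lifetimes x n_wavelengths matrix, absorbance units).
#' @export
predict_das <- function(scheme, wavelengths) {
  stopifnot(inherits(scheme, "photocycle_scheme"))
  if (length(wavelengths) == 0) stop("wavelength list must be non-empty")
  ed <- scheme_eigen(scheme)
  lam <- ed$values[ed$kinetic]
  if (length(lam) > 1) {
    d <- abs(outer(lam, lam, "-")) / max(abs(lam))
    if (min(d[upper.tri(d)]) < 1e-9)
      stop("degenerate kinetic eigenvalues; perturb nearly-equal rates")
  }
  de <- delta_extinction(scheme, wavelengths)  # states x nm
  w <- as.vector(ed$Vinv %*% scheme$initial_populations)
  scale <- scheme$concentration * scheme$pathlength * scheme$excited_fraction
  # DAS_i(lambda) = scale * sum_s de[s, lambda] * V[s, i] * w_i
  das <- Re(t(t(de) %*% ed$vectors) * w) * scale
  das <- das[ed$kinetic, , drop = FALSE]
  tau <- Re(-1 / lam)
  ord <- order(tau)
  list(lifetimes = tau[ord],
       das = das[ord, , drop = FALSE])
}

#' Peak transient occupancy of a linearly fed and drained intermediate
#'
#' For a sequential step A -> B -> C with formation rate `k_formation` and
#' decay rate `k_decay`, the maximum fractional population of B is
#' (k1/k2)^(k2/(k2-k1)) for unequal rates and 1/e in the matched-rate limit.
#' This is the quantitative form of the kinetic-invisibility argument for the
#' M intermediate: when formation and decay are similarly fast the state never
#' accumulates enough to register in transient spectra.
#'
#' @param k_formation,k_decay rate constants in s^-1, both > 0.
#' @return peak fractional population of the intermediate, in (0, 1].
#' @examples
#' max_transient_occupancy(1, 1)      # 1/e
#' max_transient_occupancy(1e6, 1)    # ~1: fast formation, slow decay
#' @export
max_transient_occupancy <- function(k_formation, k_decay) {
  stopifnot(is.numeric(k_formation), is.numeric(k_decay))
  if (any(k_formation <= 0) || any(k_decay <= 0))
    stop("both rate constants must be > 0")
  r <- k_formation / k_decay
  out <- ifelse(abs(r - 1) < 1e-12,
                exp(-1),
                exp(log(r) * (k_decay / (k_decay - k_formation))))
  unname(out)
}

#' Photostationary pump current with a blue-light M-state shunt
#'
#' Augments a photocycle scheme with continuous actinic excitation (ground ->
#' cycle entry at `green_rate`) and a blue-light driven shunt that returns the
#' M-like intermediate directly to the ground state at `blue_rate *
#' shunt_branch_ratio`, bypassing the proton-release steps. The photostationary
#' state is the null space of the augmented rate matrix; the pumped current is
#' proportional to the steady-state flux through the intermediate's normal
#' (productive) decay, and is reported relative to the `blue_rate = 0` current.
#' Exciting M with blue light therefore short-circuits the cycle and reduces
#' the current, which is the signature used to demonstrate a kinetically
#' hidden M state in bilayer photocurrent measurements.
#'
#' @param scheme a [photocycle_scheme()].
#' @param green_rate actinic excitation rate of the ground state, s^-1; > 0.
#' @param blue_rate blue-light excitation rate of the shunted state, s^-1.
#' @param shunt_branch_ratio fraction of blue-light excitations of the shunted
#'   state that return it to the ground state; in [0, 1].
#' @param shunt_state name of the M-like state. Defaults to a state named
#'   `"M"`, else the second intermediate along the cycle entry.
#' @return relative pump current (1 at `blue_rate = 0`, smaller otherwise).
#' @export
steady_state_current <- function(scheme, green_rate, blue_rate,
                                 shunt_branch_ratio, shunt_state = NULL) {
  stopifnot(inherits(scheme, "photocycle_scheme"))
  if (green_rate <= 0)
    stop("green_rate must be > 0: with no actinic excitation there is no ",
         "steady-state flux")
  if (blue_rate < 0) stop("blue_rate must be >= 0")
  if (shunt_branch_ratio < 0 || shunt_branch_ratio > 1)
    stop("shunt_branch_ratio must lie in [0, 1]")
  nm <- names(scheme$states)
  if (is.null(shunt_state)) {
    shunt_state <- if ("M" %in% nm) "M" else {
      inter <- setdiff(nm, scheme$ground)
      if (length(inter) < 2) inter[1] else inter[2]
    }
  }
  if (!shunt_state %in% nm || shunt_state == scheme$ground)
    stop("shunt_state must name an intermediate of the scheme")
  g <- scheme$ground
  flux_at <- function(b) {
    K <- scheme$rate_matrix
    # actinic pumping of the ground state into the cycle entry distribution
    entry <- scheme$initial_populations
    K[, g] <- K[, g] + green_rate * entry
    K[g, g] <- K[g, g] - green_rate
    # blue-light shunt M -> ground, skipping proton release
    K[g, shunt_state] <- K[g, shunt_state] + b * shunt_branch_ratio
    K[shunt_state, shunt_state] <- K[shunt_state, shunt_state] -
      b * shunt_branch_ratio
    sv <- svd(K)
    css <- abs(sv$v[, ncol(K)])
    css <- css / sum(css)
    names(css) <- nm
    # productive flux: normal first-order decay of the shunted state
    k_out <- scheme$rate_matrix[, shunt_state]
    k_out[shunt_state] <- 0
    sum(k_out) * css[shunt_state]
  }
  unname(flux_at(blue_rate) / flux_at(0))
}
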