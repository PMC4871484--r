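#' Global multi-exponential fit of a reduced trace set
#'
#' Fits all wavelengths simultaneously to a sum of exponentials with shared
#' lifetimes and per-wavelength amplitudes,
#' deltaA(lambda, t) = sum_i A_i(lambda) exp(-t / tau_i),
#' minimizing the summed squared residual over every wavelength and time point.
#' The amplitude matrix (the decay-associated spectra, DAS) is eliminated by
#' linear least squares at each trial lifetime set (variable projection), so the
#' nonlinear search runs only over the lifetimes, parameterized as log(tau) to
#' enforce positivity. When no initial lifetimes are supplied, a multistart
#' strategy is used: one evenly log-spaced start plus starts drawn log-uniformly
#' from [2 min dt, 2 max t] under a fixed internal seed, keeping the best
#' optimum. No additive offset is fitted by default, since a complete photocycle
#' recovers the ground state and the transient decays to zero; set
#' `offset = TRUE` to relax this.
#'
#' @param data a `reduced_trace_set` (or raw `trace_set`).
#' @param n_exponentials number of exponential components to fit.
#' @param init optional numeric vector of initial lifetimes (seconds); when
#'   given, multistart is skipped.
#' @param offset fit an additive per-wavelength constant as well.
#' @param weighting `"none"` (default, as in unweighted global fitting) or
#'   `"block"`, which weights each reduced point by the square root of its
#'   averaging block size (inverse standard deviation of the block mean).
#' @param n_starts number of multistart initializations.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param ftol relative cost-change convergence tolerance.
#' @return an object of class `global_fit`: `lifetimes` (seconds, ascending),
#'   `das` (n_exponentials x n_wavelengths), optional `offset_das`,
#'   `residual_rms`, `n_exponentials`, `converged`, `lifetime_rel_se`
#'   (relative standard error per lifetime, from the variable-projection
#'   Jacobian), `rss` and `wavelengths`.
#' @examples
#' acq <- default_acquisition(n_samples_per_scope = 2048, noise_sd = 0, seed = 1)
#' ds <- make_photocycle_dataset(e17r_scheme(), acq)
#' red <- merge_traces(reduce_log_blocks(ds$fast), reduce_log_blocks(ds$slow))
#' fit <- fit_global(red, 4)
#' signif(fit$lifetimes, 3)
#' @export
fit_global <- function(data, n_exponentials, init = NULL, offset = FALSE,
                       weighting = c("none", "block"), n_starts = 5,
                       max_iter = 500, ftol = 1e-10) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(data, c("reduced_trace_set", "trace_set")))
  n <- as.integer(n_exponentials)
  if (n < 1) stop("n_exponentials must be >= 1")
  t <- data$times
  Y <- t(data$delta_A)                       # times x wavelengths
  if (n + offset >= length(t))
    stop("more exponentials than time points")
  w <- rep(1, length(t))
  if (weighting == "block") {
    bs <- data$provenance$block_sizes
    if (is.null(bs) || length(bs) != length(t))
      stop("block weighting requires reduction provenance with block sizes")
    w <- sqrt(bs)
  }
  design <- function(logtau) {
    X <- exp(-outer(t, exp(-logtau)))        # exp(-t/tau)
    if (offset) X <- cbind(X, 1)
    X
  }
  resid_fun <- function(logtau) {
    X <- design(logtau) * w
    A <- qr.coef(qr(X), Y * w)
    as.vector(Y * w - X %*% A)
  }
  starts <- if (!is.null(init)) {
    if (length(init) != n) stop("init must supply one lifetime per exponential")
    if (any(init <= 0)) stop("initial lifetimes must be > 0")
    list(log(sort(init)))
  } else {
    lo <- log(2 * min(diff(t)))
    hi <- log(2 * max(t))
    s <- list(seq(lo, hi, length.out = max(n, 2))[seq_len(n)])
    extra <- with_seed(20L, replicate(max(0L, n_starts - 1L),
                                      sort(runif(n, lo, hi)),
                                      simplify = FALSE))
    c(s, extra)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = ftol, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("global fit failed from every start")
  logtau <- best$par
  X <- design(logtau) * w
  A <- qr.coef(qr(X), Y * w)                 # (n[+1]) x wavelengths
  R <- Y - design(logtau) %*% A
  tau <- exp(logtau)
  ord <- order(tau)
  das <- A[seq_len(n), , drop = FALSE][ord, , drop = FALSE]
  colnames(das) <- as.character(data$wavelengths)
  # relative standard error of each lifetime from the projected Jacobian
  rel_se <- rep(NA_real_, n)
  sigma2 <- best$deviance / max(1, length(t) * ncol(Y) - n * (1 + ncol(Y)))
  J <- tryCatch({
    eps <- 1e-6
    vapply(seq_len(n), function(i) {
      dp <- logtau; dm <- logtau
      dp[i] <- dp[i] + eps; dm[i] <- dm[i] - eps
      (resid_fun(dp) - resid_fun(dm)) / (2 * eps)
    }, numeric(length(t) * ncol(Y)))
  }, error = function(e) NULL)
  if (!is.null(J)) {
    cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cv)) rel_se <- sqrt(pmax(diag(cv), 0))[ord]  # se of log tau
  }
  structure(list(lifetimes = tau[ord],
                 das = das,
                 offset_das = if (offset) A[n + 1L, ] else NULL,
                 residual_rms = sqrt(mean(R^2)),
                 n_exponentials = n,
                 converged = best$info %in% 1:4,
                 lifetime_rel_se = rel_se,
                 rss = sum(R^2),
                 wavelengths = data$wavelengths),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("global fit: %d exponentials over %d wavelengths%s\n",
              x$n_exponentials, length(x$wavelengths),
              if (x$converged) "" else " (NOT converged)"))
  cat("lifetimes (s):", paste(signif(x$lifetimes, 4), collapse = ", "), "\n")
  cat(sprintf("residual rms: %.3g OD\n", x$residual_rms))
  invisible(x)
}

#' Back-extrapolated flash-time amplitude at one wavelength
#'
#' The fitted model evaluated at t -> 0+, i.e. the sum of all decay-associated
#' amplitudes at the requested wavelength. For a complete fit this equals the
#' transient absorbance immediately after the flash.
#'
#' @param result a [fit_global()] result.
#' @param wavelength probe wavelength (must be one of the fitted wavelengths).
#' @return the summed DAS amplitude at that wavelength (absorbance units).
#' @export
reconstruct_initial_amplitude <- function(result, wavelength) {
  stopifnot(inherits(result, "global_fit"))
  j <- which(abs(result$wavelengths - wavelength) < 1e-9)
  if (length(j) != 1L)
    stop("wavelength ", wavelength, " nm is not among the fitted wavelengths")
  unname(colSums(result$das)[j])
}

#' Choose the number of exponential components
#'
#' Fits 1 to `max_n` exponentials and selects the most parsimonious count: the
#' largest model is truncated at the first component whose addition improves
#' the residual rms by less than `threshold` (relative). A per-n report is
#' returned alongside the chosen count.
#'
#' @param data a `reduced_trace_set`.
#' @param max_n largest component count tried; >= 1.
#' @param threshold minimal relative rms improvement that justifies one more
#'   component (default 0.05).
#' @param ... passed to [fit_global()].
#' @return list with `n_selected`, `report` (data.frame n / residual_rms /
#'   rel_improvement), and `fits` (one [fit_global()] result per n).
#' @export
select_n_exponentials <- function(data, max_n, threshold = 0.05, ...) {
  max_n <- as.integer(max_n)
  if (max_n < 1) stop("max_n must be >= 1")
  fits <- lapply(seq_len(max_n), function(n) fit_global(data, n, ...))
  rms <- vapply(fits, `[[`, numeric(1), "residual_rms")
  impr <- c(NA_real_, if (max_n > 1) 1 - rms[-1] / rms[-max_n])
  # once the residual is at numerical noise relative to the data, further
  # components cannot be meaningful however the rms ratio behaves
  floor_rms <- 1e-9 * sqrt(mean(data$delta_A^2))
  prev_rms <- c(NA_real_, rms[-max_n])
  weak <- which(impr < threshold | prev_rms < floor_rms)
  n_sel <- if (length(weak)) max(1L, min(weak) - 1L) else max_n
  list(n_selected = n_sel,
       report = data.frame(n = seq_len(max_n), residual_rms = rms,
                           rel_improvement = impr),
       fits = fits)
}
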