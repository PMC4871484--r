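#' Logarithmic block reduction of a uniformly sampled trace set
#'
#' Oscilloscope traces are recorded on a uniform time base, but photocycle
#' kinetics span many decades; before global fitting the raw points are
#' compressed by century-wise block averaging. The n-th "century" emits a fixed
#' number of reduced points (`points_per_century`, default 100), each the exact
#' arithmetic mean of 2^(n-1) consecutive raw samples, so the block size doubles
#' from century to century and the reduced time base is approximately
#' logarithmic. The final, partial century emits as many full blocks as fit;
#' an incomplete tail block is discarded. Each reduced time stamp is the mean
#' of its block's sample times. Under this scheme a 46080-sample trace reduces
#' to exactly 880 points (8 full centuries of 100 plus 80 blocks of 256).
#'
#' @param raw a `trace_set` with a uniform time base (constant step to 1 part
#'   in 1e9).
#' @param points_per_century reduced points emitted per full century.
#' @return an object of class `reduced_trace_set`: `times`, `delta_A`
#'   (wavelengths x reduced times), `wavelengths`, and `provenance` (source
#'   step, the block size of every reduced point, and raw samples consumed).
#' @examples
#' acq <- default_acquisition(n_samples_per_scope = 300, noise_sd = 0, seed = 1)
#' ds <- make_photocycle_dataset(e17r_scheme(), acq)
#' reduce_log_blocks(ds$fast)   # 300 samples -> 200 points
#' @export
reduce_log_blocks <- function(raw, points_per_century = 100) {
  stopifnot(inherits(raw, "trace_set"))
  if (points_per_century < 1) stop("points_per_century must be >= 1")
  points_per_century <- as.integer(points_per_century)
  n <- length(raw$times)
  if (n == 0) stop("empty trace")
  if (n > 1) {
    dts <- diff(raw$times)
    if (max(dts) - min(dts) > 1e-9 * max(dts))
      stop("raw trace must have a uniform time base")
  }
  sizes <- integer(0)   # block size of every emitted point
  consumed <- 0L
  century <- 1L
  repeat {
    bs <- bitwShiftL(1L, century - 1L)   # 2^(century-1), kept integer
    remaining <- n - consumed
    if (remaining < bs) break
    nb <- min(points_per_century, as.integer(remaining %/% bs))
    sizes <- c(sizes, rep.int(bs, nb))
    consumed <- consumed + nb * bs
    if (nb < points_per_century) break   # partial century: tail discarded
    century <- century + 1L
  }
  grp <- rep.int(seq_along(sizes), sizes)
  idx <- seq_len(consumed)
  times <- as.vector(rowsum(raw$times[idx], grp)) / sizes
  vals <- t(rowsum(t(raw$delta_A[, idx, drop = FALSE]), grp) / sizes)
  dimnames(vals) <- list(as.character(raw$wavelengths), NULL)
  structure(list(times = times, delta_A = vals,
                 wavelengths = raw$wavelengths,
                 provenance = list(source_dt = if (n > 1) raw$times[2] - raw$times[1] else NA_real_,
                                   points_per_century = points_per_century,
                                   block_sizes = sizes,
                                   raw_samples = n, raw_consumed = consumed)),
            class = "reduced_trace_set")
}

#' @export
print.reduced_trace_set <- function(x, ...) {
  cat(sprintf("reduced trace set: %d wavelengths x %d points, t in [%.3g, %.3g] s\n",
              nrow(x$delta_A), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Merge reduced fast and slow oscilloscope traces
#'
#' Combines the two logarithmically reduced time bases into one dataset: all
#' fast points are kept, followed by those slow points whose block-center time
#' strictly exceeds the last fast time. For the default acquisition (two
#' 46080-sample traces at 200 ns and 20 us per point, 880 reduced points each)
#' the merge yields 1520 points covering the range up to about one second.
#'
#' @param fast,slow `reduced_trace_set` objects on identical wavelength axes;
#'   `fast` must end before `slow` does.
#' @return a merged `reduced_trace_set` with strictly increasing times.
#' @export
merge_traces <- function(fast, slow) {
  stopifnot(inherits(fast, "reduced_trace_set"),
            inherits(slow, "reduced_trace_set"))
  if (length(fast$wavelengths) != length(slow$wavelengths) ||
      any(fast$wavelengths != slow$wavelengths))
    stop("fast and slow traces must share the same wavelength axis")
  t_cut <- max(fast$times)
  if (max(slow$times) <= t_cut)
    stop("slow trace must extend beyond the fast trace")
  keep <- slow$times > t_cut
  structure(list(times = c(fast$times, slow$times[keep]),
                 delta_A = cbind(fast$delta_A, slow$delta_A[, keep, drop = FALSE]),
                 wavelengths = fast$wavelengths,
                 provenance = list(fast = fast$provenance, slow = slow$provenance,
                                   n_fast = length(fast$times),
                                   n_slow_kept = sum(keep),
                                   block_sizes = c(fast$provenance$block_sizes,
                                                   slow$provenance$block_sizes[keep]))),
            class = "reduced_trace_set")
}
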