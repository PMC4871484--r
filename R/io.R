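format_sig9 <- function(x) formatC(x, digits = 9, format = "g")

#' Write / read trace sets as TSV
#'
#' Trace sets (raw or reduced) travel as tab-separated text: first column
#' `time_s`, remaining columns headed by the integer probe wavelength in nm,
#' values printed with 9 significant digits (a lossless round-trip at that
#' precision). Lines starting with `#` are metadata comments (e.g. the pipeline
#' config hash) and are skipped on read.
#'
#' @param ts a `trace_set` or `reduced_trace_set`.
#' @param path output file path.
#' @param comment optional character vector written as leading `# ` lines.
#' @return `write_trace_tsv`: the path, invisibly.
#' @export
write_trace_tsv <- function(ts, path, comment = NULL) {
  stopifnot(inherits(ts, c("trace_set", "reduced_trace_set")))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(paste(c("time_s", as.character(round(ts$wavelengths))),
                   collapse = "\t"), con)
  body <- cbind(format_sig9(ts$times),
                matrix(format_sig9(t(ts$delta_A)), nrow = length(ts$times)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @param path TSV file path.
#' @param reduced return a `reduced_trace_set` (non-uniform time base allowed)
#'   instead of a raw `trace_set`.
#' @return `read_trace_tsv`: a `trace_set` (or `reduced_trace_set`).
#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path, reduced = FALSE) {
  lines <- readLines(path)
  skip <- sum(cumprod(startsWith(lines, "#")))
  hdr <- strsplit(lines[skip + 1L], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "time_s")
    stop("not a trace TSV: first column must be 'time_s'")
  wl <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(wl)) stop("non-numeric wavelength column header")
  body <- lines[-seq_len(skip + 1L)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(hdr)))
    stop("ragged row at line ", skip + 1L + which(nf != length(hdr))[1])
  m <- matrix(as.numeric(unlist(parts)), ncol = length(hdr), byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value in trace body")
  times <- m[, 1]
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop("non-increasing time at line ", skip + 2L + bad[1])
  dA <- t(m[, -1, drop = FALSE])
  if (reduced)
    structure(list(times = times, delta_A = dA, wavelengths = wl,
                   provenance = list(source = path)),
              class = "reduced_trace_set")
  else
    trace_set(times, dA, wl)
}

#' Write / read a photocycle scheme as JSON
#'
#' @param scheme a [photocycle_scheme()].
#' @param path JSON file path.
#' @return `read_scheme_json`: a [photocycle_scheme()].
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "photocycle_scheme"))
  obj <- list(
    states = lapply(scheme$states, unclass),
    rate_matrix = scheme$rate_matrix,
    initial_populations = as.list(scheme$initial_populations),
    ground = scheme$ground,
    excited_fraction = scheme$excited_fraction,
    concentration = scheme$concentration,
    pathlength = scheme$pathlength)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- lapply(obj$states, function(s)
    spectral_band(s$center, s$width, s$peak_extinction, s$skew))
  K <- as.matrix(obj$rate_matrix)
  dimnames(K) <- list(names(states), names(states))
  photocycle_scheme(states, K, unlist(obj$initial_populations), obj$ground,
                    excited_fraction = obj$excited_fraction,
                    concentration = obj$concentration,
                    pathlength = obj$pathlength)
}

#' Pipeline configuration
#'
#' Bundles everything the end-to-end flash-photolysis pipeline needs: the
#' kinetic scheme, the acquisition geometry, the reduction and fit parameters,
#' the output directory and the single seed from which all randomness flows.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed; recorded in every output.
#' @param scheme a [photocycle_scheme()].
#' @param acquisition an [default_acquisition()] config; its seed is overridden
#'   by `seed`.
#' @param points_per_century reduction parameter, see [reduce_log_blocks()].
#' @param n_exponentials number of exponentials for [fit_global()].
#' @param offset,weighting passed to [fit_global()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, scheme = e17r_scheme(),
                            acquisition = default_acquisition(),
                            points_per_century = 100, n_exponentials = 4,
                            offset = FALSE, weighting = "none") {
  acquisition$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed), scheme = scheme,
                 acquisition = acquisition,
                 points_per_century = points_per_century,
                 n_exponentials = n_exponentials,
                 offset = offset, weighting = weighting),
            class = "pipeline_config")
}

# md5 of the config's JSON serialization (timestamps excluded by construction)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- list(seed = config$seed,
              scheme = list(states = lapply(config$scheme$states, unclass),
                            rate_matrix = config$scheme$rate_matrix,
                            initial_populations = config$scheme$initial_populations,
                            ground = config$scheme$ground,
                            excited_fraction = config$scheme$excited_fraction,
                            concentration = config$scheme$concentration,
                            pathlength = config$scheme$pathlength),
              acquisition = unclass(config$acquisition),
              points_per_century = config$points_per_century,
              n_exponentials = config$n_exponentials,
              offset = config$offset, weighting = config$weighting)
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full flash-photolysis analysis pipeline
#'
#' simulate -> reduce -> merge -> global fit -> report. Writes the raw fast and
#' slow trace sets, the merged reduced dataset, the DAS table and a JSON report
#' (recovered lifetimes, diagnostics, seed, config hash, package version) into
#' `config$outdir`. Every output file embeds the config hash, so reruns with an
#' identical configuration are byte-identical apart from nothing — the report
#' carries no timestamps.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress to standard error.
#' @return list with `fit` (the [fit_global()] result), `merged` (the reduced
#'   dataset), `report` (the report list) and `paths` of all files written.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  hash <- config_hash(config)
  meta_comment <- sprintf("config_hash=%s seed=%d", hash, config$seed)
  p <- function(f) file.path(config$outdir, f)

  log_stage("simulate", "generating dual-oscilloscope trace sets")
  ds <- tryCatch(make_photocycle_dataset(config$scheme, config$acquisition),
                 error = function(e) stop("[simulate] ", conditionMessage(e)))
  write_trace_tsv(ds$fast, p("trace_fast.tsv"), comment = meta_comment)
  write_trace_tsv(ds$slow, p("trace_slow.tsv"), comment = meta_comment)

  log_stage("reduce", "logarithmic block reduction")
  red <- tryCatch(list(fast = reduce_log_blocks(ds$fast, config$points_per_century),
                       slow = reduce_log_blocks(ds$slow, config$points_per_century)),
                  error = function(e) stop("[reduce] ", conditionMessage(e)))

  log_stage("merge", "merging fast and slow time bases")
  merged <- tryCatch(merge_traces(red$fast, red$slow),
                     error = function(e) stop("[merge] ", conditionMessage(e)))
  write_trace_tsv(merged, p("trace_merged.tsv"), comment = meta_comment)

  log_stage("globalfit", sprintf("fitting %d exponentials", config$n_exponentials))
  fit <- tryCatch(fit_global(merged, config$n_exponentials,
                             offset = config$offset,
                             weighting = config$weighting),
                  error = function(e) stop("[globalfit] ", conditionMessage(e)))

  das_path <- p("das.tsv")
  das_tab <- cbind(wavelength_nm = fit$wavelengths,
                   as.data.frame(t(signif(fit$das, 9))))
  names(das_tab)[-1] <- sprintf("tau_%s_s", format_sig9(fit$lifetimes))
  con <- file(das_path, "w")
  writeLines(paste0("# ", meta_comment), con)
  close(con)
  suppressWarnings(utils::write.table(das_tab, das_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  report <- list(config_hash = hash, seed = config$seed,
                 package_version = as.character(utils::packageVersion("photocyclr")),
                 n_points_merged = length(merged$times),
                 lifetimes_s = fit$lifetimes,
                 lifetime_rel_se = fit$lifetime_rel_se,
                 residual_rms = fit$residual_rms,
                 converged = fit$converged,
                 das_table = basename(das_path))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("report", sprintf("lifetimes: %s s",
                              paste(signif(fit$lifetimes, 4), collapse = ", ")))
  list(fit = fit, merged = merged, report = report,
       paths = c(fast = p("trace_fast.tsv"), slow = p("trace_slow.tsv"),
                 merged = p("trace_merged.tsv"), das = das_path,
                 report = p("report.json")))
}
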