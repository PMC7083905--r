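# File formats: TIFF movies with YAML metadata sidecars, CSV tables with
# fixed schemas, JSON fit results. All times seconds, frames 0-based,
# pixel coordinates 0-based from the top-left pixel centre.

protocolToList <- function(protocol, conditionIndex = NULL) {
  out <- list(tau_int_s = protocol@tauInt,
              tau_d_s = protocol@tauD,
              n_bleach_frames = protocol@nBleachFrames,
              n_frames = protocol@nFrames,
              pixel_size_nm = protocol@pixelSizeNm,
              field_shape = protocol@fieldShape)
  if (!is.null(conditionIndex))
    out$condition_index <- as.integer(conditionIndex)
  out
}

listToProtocol <- function(meta) {
  need <- c("tau_int_s", "tau_d_s", "n_bleach_frames", "n_frames",
            "pixel_size_nm", "field_shape")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("metadata is missing required field(s): ",
         paste(missing, collapse = ", "))
  acquisitionProtocol(tauInt = meta$tau_int_s,
                      tauD = unlist(meta$tau_d_s),
                      nBleachFrames = meta$n_bleach_frames,
                      nFrames = meta$n_frames,
                      pixelSizeNm = meta$pixel_size_nm,
                      fieldShape = unlist(meta$field_shape))
}

sidecarPath <- function(path) sub("\\.tiff?$", ".yaml", path)

#' Write / read a movie stack with its metadata sidecar
#'
#' Movies are stored as multi-page 16-bit TIFF (one file per condition)
#' with the acquisition metadata — exposure, the full dark-interval
#' schedule, phase lengths, pixel size and the movie's condition index —
#' in a YAML sidecar next to the TIFF (`.tif` replaced by `.yaml`).
#' Intensities are rounded to integer counts on write.
#'
#' @param movie A [MovieStack-class].
#' @param path TIFF output path.
#' @param metaPath Sidecar path; defaults to `path` with a `.yaml`
#'   extension.
#' @return `writeMovie()` returns `path` invisibly; `readMovie()` returns
#'   a [MovieStack-class].
#' @export
writeMovie <- function(movie, path, metaPath = sidecarPath(path)) {
  stopifnot(is(movie, "MovieStack"))
  n <- dim(movie@frames)[3]
  pages <- lapply(seq_len(n), function(i)
    pmin(pmax(round(movie@frames[, , i]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(protocolToList(movie@protocol, movie@conditionIndex),
                   metaPath)
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path, metaPath = sidecarPath(path)) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  if (!file.exists(metaPath))
    stop("no metadata sidecar at '", metaPath, "': supply the acquisition ",
         "protocol as a YAML file with fields tau_int_s, tau_d_s, ",
         "n_bleach_frames, n_frames, pixel_size_nm, field_shape and ",
         "condition_index, or pass its path as 'metaPath'")
  meta <- yaml::read_yaml(metaPath)
  protocol <- listToProtocol(meta)
  if (is.null(meta$condition_index))
    stop("metadata sidecar lacks 'condition_index'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * 65535)
  new("MovieStack", frames = arr, protocol = protocol,
      conditionIndex = as.integer(meta$condition_index),
      noiseParams = list())
}

readTable <- function(path, schema, what) {
  if (!file.exists(path)) stop(what, " table not found: ", path)
  checkSchema(read.csv(path), schema, what)
}

#' Read and write the pipeline's flat tables
#'
#' CSV round-trips for the focus, binding-event, dwell and CRTD tables.
#' Each reader validates the schema and names any missing column. The CRTD
#' table uses columns `condition_id`, `tau_int_s`, `tau_d_s`, `t_s`,
#' `count` — the layout a per-condition CRTD export (e.g. a journal
#' source-data sheet) provides — and is returned as a list of
#' [CRTD-class] objects.
#'
#' @param x Table (data.frame) or, for `writeCrtdTable()`, a list of
#'   [CRTD-class] objects.
#' @param path CSV path.
#' @return Readers return validated data.frames (or CRTD lists); writers
#'   return `path` invisibly.
#' @export
readFociTable <- function(path) readTable(path, fociSchema, "focus")

#' @rdname readFociTable
#' @export
writeFociTable <- function(x, path) {
  checkSchema(x, fociSchema, "focus")
  write.csv(x[fociSchema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname readFociTable
#' @export
readEventsTable <- function(path) readTable(path, eventSchema, "event")

#' @rdname readFociTable
#' @export
writeEventsTable <- function(x, path) {
  checkSchema(x, eventSchema, "event")
  write.csv(x[eventSchema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname readFociTable
#' @export
readDwellTable <- function(path) readTable(path, dwellSchema, "dwell")

#' @rdname readFociTable
#' @export
writeDwellTable <- function(x, path) {
  checkSchema(x, dwellSchema, "dwell")
  write.csv(x[dwellSchema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname readFociTable
#' @export
readCrtdTable <- function(path) {
  df <- readTable(path, crtdSchema, "CRTD")
  lapply(split(df, df$condition_id), function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    new("CRTD", conditionId = as.integer(d$condition_id[1]),
        tauInt = d$tau_int_s[1], tauD = d$tau_d_s[1],
        time = d$t_s, counts = as.numeric(d$count),
        totalEvents = as.integer(max(d$count)))
  })
}

#' @rdname readFociTable
#' @export
writeCrtdTable <- function(x, path) {
  if (is(x, "CRTD")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(cr)
    data.frame(condition_id = cr@conditionId, tau_int_s = cr@tauInt,
               tau_d_s = cr@tauD, t_s = cr@time, count = cr@counts)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a global fit result
#'
#' `writeFitJson()` stores the full fit (parameters, per-condition scales,
#' convergence diagnostics and the bootstrap distribution) as JSON.
#' `fitSummaryTable()` flattens a fit into one row per kinetic population
#' with bootstrap mean +/- SD for the lifetime and the population
#' percentage — the layout of a lifetimes summary table; `writeFitSummary()`
#' writes it as CSV.
#'
#' @param fit A [GlobalFitResult-class].
#' @param path Output path.
#' @param label Sample label for the summary row(s).
#' @return `fitSummaryTable()` returns a data.frame; the writers return
#'   `path` invisibly.
#' @export
writeFitJson <- function(fit, path) {
  stopifnot(is(fit, "GlobalFitResult"))
  out <- list(model_order = fit@modelOrder, kb_per_s = fit@kb,
              koff_per_s = fit@koff, lifetimes_s = 1 / fit@koff,
              amplitudes = fit@amplitudes, scales = fit@scales,
              rss = fit@rss, n_points = fit@nPoints,
              n_events = fit@nEvents, conditions = fit@conditions,
              converged = fit@converged, optimizer_info = fit@info,
              optimizer_message = fit@message,
              bootstrap_samples = fit@bootstrapSamples,
              bootstrap_summary = fit@bootstrapSummary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeFitJson
#' @export
fitSummaryTable <- function(fit, label = "sample") {
  stopifnot(is(fit, "GlobalFitResult"))
  bs <- fit@bootstrapSummary
  get <- function(p, what) {
    if (nrow(bs) && p %in% bs$parameter) bs[[what]][bs$parameter == p]
    else NA_real_
  }
  lifeSlow <- if (is.na(get("lifetime_slow", "mean"))) 1 / fit@koff[1]
              else get("lifetime_slow", "mean")
  out <- data.frame(
    label = label, model_order = fit@modelOrder,
    slow_lifetime_s = lifeSlow,
    slow_lifetime_sd_s = get("lifetime_slow", "sd"),
    slow_percent = 100 * (if (is.na(get("amplitude_slow", "mean")))
      fit@amplitudes[1] else get("amplitude_slow", "mean")),
    slow_percent_sd = 100 * get("amplitude_slow", "sd"),
    fast_lifetime_s = NA_real_, fast_lifetime_sd_s = NA_real_,
    kb_per_s = fit@kb)
  if (fit@modelOrder == 2L) {
    out$fast_lifetime_s <- if (is.na(get("lifetime_fast", "mean")))
      1 / fit@koff[2] else get("lifetime_fast", "mean")
    out$fast_lifetime_sd_s <- get("lifetime_fast", "sd")
  }
  out
}

#' @rdname writeFitJson
#' @export
writeFitSummary <- function(fit, path, label = "sample") {
  write.csv(fitSummaryTable(fit, label), path, row.names = FALSE)
  invisible(path)
}
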