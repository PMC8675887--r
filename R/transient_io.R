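#' Construct a fluorescence transient
#'
#' A fluorescence transient holds one sample's time-resolved chlorophyll-a
#' fluorescence rise (OJIP curve) recorded after dark adaptation: acquisition
#' times in seconds and fluorescence in instrument arbitrary units.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param times Numeric vector of acquisition times in seconds; strictly
#'   increasing, all positive, length at least 4.
#' @param fluorescence Numeric vector of fluorescence intensities (a.u.),
#'   same length as `times`; finite and non-negative.
#' @return An object of class `fluor_transient`.
#' @export
fluorescence_transient <- function(sample_id, times, fluorescence) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id))
    stop("sample_id must be a single character label")
  times <- as.numeric(times)
  fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence))
    stop(sprintf("sample '%s': times and fluorescence differ in length", sample_id))
  if (length(times) < 4L)
    stop(sprintf("sample '%s': at least 4 timepoints required", sample_id))
  if (anyNA(times) || any(!is.finite(times)) || any(times <= 0))
    stop(sprintf("sample '%s': times must be finite and positive", sample_id))
  if (any(diff(times) <= 0))
    stop(sprintf("sample '%s': times must be strictly increasing", sample_id))
  if (anyNA(fluorescence) || any(!is.finite(fluorescence)) || any(fluorescence < 0))
    stop(sprintf("sample '%s': fluorescence must be finite and non-negative", sample_id))
  structure(list(sample_id = sample_id, times = times, fluorescence = fluorescence),
            class = "fluor_transient")
}

#' @export
print.fluor_transient <- function(x, ...) {
  cat(sprintf("<fluor_transient '%s': %d points, %.3g-%.3g s, F %.4g-%.4g a.u.>\n",
              x$sample_id, length(x$times), min(x$times), max(x$times),
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

.time_factor <- function(time_unit) {
  switch(match.arg(time_unit, c("s", "ms", "us")),
         s = 1, ms = 1e-3, us = 1e-6)
}

#' Read fluorescence transients from a delimited table
#'
#' Supports the two layouts common to continuous-excitation fluorometer
#' exports: long (`sample_id`, `time_s`, `fluorescence`) and wide (`time_s`
#' plus one column per sample). The delimiter (tab or comma) is
#' auto-detected. Rows are sorted by time; duplicated timepoints keep the
#' first occurrence with a warning.
#'
#' @param path Path to a delimited text file.
#' @param layout `"long"` or `"wide"`.
#' @param time_unit Unit of the time column: `"s"` (default), `"ms"` or
#'   `"us"`; values are converted to seconds on ingest.
#' @return A named list of [fluorescence_transient()] objects.
#' @export
read_transients <- function(path, layout = c("long", "wide"), time_unit = "s") {
  layout <- match.arg(layout)
  fac <- .time_factor(time_unit)
  tab <- utils::read.delim(path, sep = .detect_delim(path), check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c("sample_id", "time_s", "fluorescence")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop(sprintf("transient table is missing required column(s): %s",
                   paste(miss, collapse = ", ")))
    pieces <- split(tab, tab$sample_id)
    out <- lapply(pieces, function(d) {
      .build_transient(d$sample_id[1L], d$time_s * fac, d$fluorescence)
    })
  } else {
    if (!"time_s" %in% names(tab))
      stop("transient table is missing required column(s): time_s")
    ids <- setdiff(names(tab), "time_s")
    if (length(ids) == 0L) stop("wide transient table has no sample columns")
    out <- lapply(ids, function(id) {
      .build_transient(id, tab$time_s * fac, tab[[id]])
    })
    names(out) <- ids
  }
  out[order(names(out))]
}

# sort by time, de-duplicate (first kept, warning), then validate
.build_transient <- function(id, times, fl) {
  ord <- order(times)
  times <- times[ord]; fl <- fl[ord]
  dup <- duplicated(times)
  if (any(dup)) {
    warning(sprintf("sample '%s': %d duplicated timepoint(s) dropped (first kept)",
                    id, sum(dup)))
    times <- times[!dup]; fl <- fl[!dup]
  }
  fluorescence_transient(as.character(id), times, fl)
}

.SEASONS <- c("summer", "winter")
.PERIODS <- c("day", "night")

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `population`, `season`, `period`,
#' `replicate`. Season must be `summer`/`winter` and period `day`/`night`;
#' the cross of population x season x period is the grouping factor used by
#' the statistics and ordination stages.
#'
#' @param path Path to a delimited (tab or comma) text file.
#' @return A data frame of validated metadata (possibly 0 rows, with a
#'   warning for an empty file).
#' @export
read_metadata <- function(path) {
  empty <- data.frame(sample_id = character(), population = character(),
                      season = character(), period = character(),
                      replicate = integer(), stringsAsFactors = FALSE)
  tab <- tryCatch(
    utils::read.delim(path, sep = .detect_delim(path), stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) {
    warning(sprintf("metadata file '%s' contains no records", path))
    return(empty)
  }
  need <- c("sample_id", "population", "season", "period", "replicate")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("metadata table is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  tab <- tab[need]
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop(sprintf("duplicated sample_id in metadata: %s",
                 paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", ")))
  bad <- setdiff(unique(tab$season), .SEASONS)
  if (length(bad))
    stop(sprintf("unknown season level(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(.SEASONS, collapse = ", ")))
  bad <- setdiff(unique(tab$period), .PERIODS)
  if (length(bad))
    stop(sprintf("unknown period level(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(.PERIODS, collapse = ", ")))
  rep_n <- suppressWarnings(as.integer(tab$replicate))
  if (anyNA(rep_n) || any(rep_n < 1L))
    stop("replicate must be a positive integer")
  tab$replicate <- rep_n
  tab
}

#' Convert illuminance (lux) to approximate PAR
#'
#' Applies the multiplicative factor 0.019 that approximates the spectral
#' power distribution of 6000 K sunlight, giving photosynthetically active
#' radiation in umol photons m^-2 s^-1. Used to put lux loggers and PAR
#' sensors on a common scale.
#'
#' @param lux Non-negative illuminance value(s) in lux.
#' @return PAR in umol photons m^-2 s^-1 (`lux * 0.019`).
#' @export
lux_to_par <- function(lux) {
  lux <- as.numeric(lux)
  if (anyNA(lux) || any(lux < 0)) stop("lux must be non-negative")
  lux * 0.019
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row, full floating precision, no quoting or
#' row names, so that tables round-trip through [utils::read.delim()].
#'
#' @param records A non-empty data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    stop("refusing to write an empty table")
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a collection of transients as a long TSV
#'
#' @param transients Named list of [fluorescence_transient()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_transients <- function(transients, path) {
  if (length(transients) == 0L) stop("refusing to write an empty table")
  long <- do.call(rbind, lapply(transients, function(tr) {
    data.frame(sample_id = tr$sample_id, time_s = tr$times,
               fluorescence = tr$fluorescence, stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  write_table(long, path)
}
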