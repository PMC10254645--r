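#' Acquisition metadata for a time-resolved analysis run
#'
#' Bundles the acquisition settings and sample bookkeeping that every
#' downstream computation needs. All quantities are held in the package's
#' canonical units — seconds, litres, grams — so unit conversion happens
#' only at the I/O boundary.
#'
#' @param dwell_time Dwell (integration) time per data point, in seconds.
#'   Default `1e-4` (100 µs), the microsecond-dwell regime in which a single
#'   particle's ion cloud spans several consecutive dwells.
#' @param total_time Total acquisition time in seconds (default 120).
#' @param isotope_label Monitored isotope, e.g. `"56Fe"`.
#' @param sample_id Free-text sample identifier.
#' @param dilution_factor Dilution applied to the analysed suspension
#'   relative to the original extract (dimensionless, >= 1).
#' @param extract_volume Volume of the extract the analysed suspension was
#'   drawn from, in litres. Default `8.5e-3` (7 mL buffer + 1.5 mL enzyme
#'   solution of a typical plant enzymatic digest).
#' @param tissue_mass Mass of digested tissue, in grams (default 0.015).
#'
#' @return An object of class `acquisition_meta` (a named list).
#' @export
#' @examples
#' meta <- acquisition_meta(total_time = 10)
#' n_dwells(meta)
acquisition_meta <- function(dwell_time = 1e-4,
                             total_time = 120,
                             isotope_label = "56Fe",
                             sample_id = "sample",
                             dilution_factor = 1,
                             extract_volume = 8.5e-3,
                             tissue_mass = 0.015) {
  stopifnot(is.numeric(dwell_time), length(dwell_time) == 1,
            is.numeric(total_time), length(total_time) == 1)
  if (dwell_time <= 0) abort("`dwell_time` must be > 0 (seconds).")
  if (total_time < dwell_time) abort("`total_time` must be >= `dwell_time`.")
  if (dilution_factor < 1) abort("`dilution_factor` must be >= 1.")
  if (extract_volume <= 0 || tissue_mass <= 0) {
    abort("`extract_volume` and `tissue_mass` must be > 0.")
  }
  structure(
    list(
      dwell_time = as.numeric(dwell_time),
      total_time = as.numeric(total_time),
      isotope_label = as.character(isotope_label),
      sample_id = as.character(sample_id),
      dilution_factor = as.numeric(dilution_factor),
      extract_volume = as.numeric(extract_volume),
      tissue_mass = as.numeric(tissue_mass)
    ),
    class = "acquisition_meta"
  )
}

#' Number of dwells implied by acquisition metadata
#'
#' @param meta An [acquisition_meta()] object.
#' @return Integer dwell count, `round(total_time / dwell_time)`.
#' @export
n_dwells <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  as.integer(round(meta$total_time / meta$dwell_time))
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat("<acquisition_meta> ", x$sample_id, " [", x$isotope_label, "]\n", sep = "")
  cat(sprintf("  dwell %g s, total %g s (%d dwells), dilution x%g\n",
              x$dwell_time, x$total_time, n_dwells(x), x$dilution_factor))
  cat(sprintf("  extract %g L, tissue %g g\n", x$extract_volume, x$tissue_mass))
  invisible(x)
}

#' Construct a time scan
#'
#' A time scan is the raw input of the pipeline: one non-negative integer
#' ion count per dwell, plus acquisition metadata. It is represented as a
#' tibble with columns `dwell` (1-based index) and `counts`, carrying the
#' metadata as an attribute, so it pipes directly into dplyr verbs.
#'
#' @param counts Non-negative integer vector, one element per dwell.
#' @param meta An [acquisition_meta()] object; its declared dwell count must
#'   match `length(counts)` to within one dwell (the declared `total_time`
#'   is then reconciled to the actual trace length).
#' @return A `timescan`: a tibble (`dwell`, `counts`) with a `meta` attribute.
#' @export
#' @examples
#' ts <- timescan(rep(0L, 100), acquisition_meta(total_time = 0.01))
timescan <- function(counts, meta = acquisition_meta(
                       total_time = length(counts) * 1e-4)) {
  if (length(counts) == 0) abort("A time scan needs at least one dwell.")
  stopifnot(inherits(meta, "acquisition_meta"))
  if (anyNA(counts)) abort("`counts` must not contain missing values.")
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort("`counts` must be integers (ion counts per dwell).")
  }
  declared <- n_dwells(meta)
  if (abs(declared - length(counts)) > 1) {
    abort(sprintf(
      "Trace has %d dwells but metadata declares %d (total_time/dwell_time); refusing to truncate.",
      length(counts), declared))
  }
  if (declared != length(counts)) {
    meta$total_time <- length(counts) * meta$dwell_time
  }
  out <- tibble::tibble(dwell = seq_along(counts),
                        counts = as.integer(round(counts)))
  structure(out, meta = meta, class = c("timescan", class(out)))
}

#' @export
#' @rdname timescan
#' @param x Object to query.
scan_meta <- function(x) {
  m <- attr(x, "meta", exact = TRUE)
  if (is.null(m)) abort("Object carries no acquisition metadata.")
  m
}

#' @export
print.timescan <- function(x, ...) {
  m <- scan_meta(x)
  cat(sprintf("<timescan> %s: %d dwells x %g s, %s\n",
              m$sample_id, nrow(x), m$dwell_time, m$isotope_label))
  NextMethod()
}

meta_fields_numeric <- c("dwell_time", "total_time", "dilution_factor",
                         "extract_volume", "tissue_mass")

#' Read a time-scan CSV
#'
#' The trace format is a plain CSV with optional `#key=value` header lines
#' carrying acquisition metadata, then a header row `index,counts`
#' (optionally with a `time_s` column), one row per dwell. Vendor exports
#' vary; this self-describing dialect is the package's interchange format.
#'
#' @param path Path to a trace CSV written by [write_timescan()] or
#'   following the same dialect.
#' @param meta_override Optional [acquisition_meta()] that replaces whatever
#'   the file header declares.
#' @return A [timescan()].
#' @export
read_timescan <- function(path, meta_override = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  head_lines <- readLines(path, n = 64L)
  header <- grep("^#", head_lines, value = TRUE)
  kv <- list()
  for (h in header) {
    h <- sub("^#\\s*", "", h)
    eq <- regexpr("=", h, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(h, 1, eq - 1))
      kv[[key]] <- trimws(substr(h, eq + 1, nchar(h)))
    }
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!"counts" %in% names(dat)) {
    abort("Trace file has no `counts` column.")
  }
  counts <- dat$counts
  if (!is.numeric(counts) || anyNA(counts) ||
      any(abs(counts - round(counts)) > 1e-9) || any(counts < 0)) {
    abort("`counts` column must hold non-negative integers.")
  }
  if (!is.null(meta_override)) {
    meta <- meta_override
  } else {
    args <- list()
    for (f in meta_fields_numeric) {
      if (!is.null(kv[[f]])) args[[f]] <- as.numeric(kv[[f]])
    }
    for (f in c("isotope_label", "sample_id")) {
      if (!is.null(kv[[f]])) args[[f]] <- kv[[f]]
    }
    if (is.null(args$dwell_time)) args$dwell_time <- 1e-4
    if (is.null(args$total_time)) {
      args$total_time <- length(counts) * args$dwell_time
    }
    meta <- do.call(acquisition_meta, args)
  }
  timescan(counts, meta)
}

#' Write a time-scan CSV
#'
#' Inverse of [read_timescan()]: metadata as `#key=value` header lines
#' (numbers at full precision so the round trip is exact), then
#' `index,counts` rows.
#'
#' @param scan A [timescan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timescan <- function(scan, path) {
  stopifnot(inherits(scan, "timescan"))
  if (nrow(scan) == 0) abort("Refusing to write an empty time scan.")
  m <- scan_meta(scan)
  hdr <- c(
    vapply(meta_fields_numeric, function(f) {
      sprintf("#%s=%s", f, format(m[[f]], digits = 17, scientific = TRUE))
    }, character(1)),
    sprintf("#isotope_label=%s", m$isotope_label),
    sprintf("#sample_id=%s", m$sample_id)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("index,counts", con)
  writeLines(paste(scan$dwell, scan$counts, sep = ","), con)
  invisible(path)
}

#' Read an ionic calibration table
#'
#' Expects columns `concentration_ug_L` and `response_cps` (extra columns
#' are ignored), one row per standard.
#'
#' @param path CSV path.
#' @return A tibble with columns `concentration_ug_L`, `response_cps`.
#' @export
read_ionic_calibration <- function(path) {
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("concentration_ug_L", "response_cps")
  if (!all(need %in% names(dat))) {
    abort("Calibration CSV needs columns `concentration_ug_L` and `response_cps`.")
  }
  tibble::as_tibble(dat[need])
}

#' Read a run-configuration JSON
#'
#' A configuration has three blocks: `instrument` (dwell_time, total_time,
#' uptake_rate, transport_efficiency, ionic_slope), `element` (density,
#' mass_fraction, isotope_abundance, molar_mass) and `sample`
#' (dilution_factor, extract_volume, tissue_mass). Missing keys fall back
#' to package defaults.
#'
#' @param path JSON file path.
#' @return A named list with elements `meta` ([acquisition_meta()]),
#'   `element` ([element_params()]) and `instrument` (named list).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  inst <- cfg$instrument %||% list()
  elem <- cfg$element %||% list()
  samp <- cfg$sample %||% list()
  meta_args <- c(
    inst[intersect(names(inst), c("dwell_time", "total_time"))],
    samp[intersect(names(samp),
                   c("dilution_factor", "extract_volume", "tissue_mass"))]
  )
  list(
    meta = do.call(acquisition_meta, meta_args),
    element = do.call(element_params, elem[intersect(
      names(elem),
      c("density_rho", "mass_fraction_X", "isotope_abundance_A", "molar_mass_M"))]),
    instrument = inst
  )
}
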