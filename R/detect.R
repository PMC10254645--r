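#' Iterative baseline estimation for a time scan
#'
#' The particle/dissolved discrimination threshold is
#' I_thresh = I_b + k * sigma_b, with I_b and sigma_b the mean and standard
#' deviation of the dissolved-signal baseline. Because raw moments are
#' contaminated by particle pulses, the baseline is purged iteratively:
#' compute mean and SD over the retained dwells, drop dwells above
#' mean + k*SD, and repeat until the retained set is stable (or `max_iter`).
#'
#' @param scan A [timescan()].
#' @param multiplier Threshold multiplier k (default 5, the usual compromise
#'   between false positives and missed true events).
#' @param max_iter Maximum purge iterations (default 20).
#' @param tol Relative change in (I_b, sigma_b) below which iteration stops
#'   even if the retained set still wobbles (default 1e-6).
#' @return A `baseline_stats` object: `I_b`, `sigma_b`, `I_thresh`
#'   (= I_b + multiplier * sigma_b), `n_baseline_dwells`, `n_iterations`,
#'   `multiplier`.
#' @export
#' @examples
#' ts <- timescan(rep(5L, 1000))
#' estimate_baseline(ts)  # I_b = 5, sigma_b = 0
estimate_baseline <- function(scan, multiplier = 5, max_iter = 20, tol = 1e-6) {
  stopifnot(inherits(scan, "timescan"), multiplier > 0)
  x <- as.numeric(scan$counts)
  retained <- rep(TRUE, length(x))
  m <- mean(x)
  s <- if (length(x) > 1) sd(x) else 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cut <- m + multiplier * s
    new_retained <- x <= cut
    if (!any(new_retained)) {
      abort("Baseline estimation excluded every dwell; trace is pathological.")
    }
    xm <- x[new_retained]
    m_new <- mean(xm)
    s_new <- if (length(xm) > 1) sd(xm) else 0
    stable_set <- identical(new_retained, retained)
    rel <- max(abs(m_new - m) / max(abs(m), 1e-12),
               abs(s_new - s) / max(abs(s), 1e-12))
    retained <- new_retained
    m <- m_new
    s <- s_new
    if (stable_set || rel < tol || iter >= max_iter) break
  }
  structure(
    list(I_b = m, sigma_b = s, I_thresh = m + multiplier * s,
         n_baseline_dwells = sum(retained), n_iterations = iter,
         multiplier = multiplier),
    class = "baseline_stats"
  )
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf(
    "<baseline_stats> I_b=%.4g, sigma_b=%.4g, I_thresh=%.4g (k=%g)\n  %d baseline dwells, %d iterations\n",
    x$I_b, x$sigma_b, x$I_thresh, x$multiplier, x$n_baseline_dwells,
    x$n_iterations))
  invisible(x)
}

#' @method glance baseline_stats
#' @export
glance.baseline_stats <- function(x, ...) {
  tibble::tibble(I_b = x$I_b, sigma_b = x$sigma_b, I_thresh = x$I_thresh,
                 multiplier = x$multiplier,
                 n_baseline_dwells = x$n_baseline_dwells,
                 n_iterations = x$n_iterations)
}

#' Detection threshold from baseline statistics
#'
#' @param stats A `baseline_stats` object from [estimate_baseline()].
#' @param multiplier Threshold multiplier (default the one used when the
#'   baseline was estimated, normally 5).
#' @return Threshold in counts per dwell, I_b + multiplier * sigma_b.
#' @export
compute_threshold <- function(stats, multiplier = stats$multiplier) {
  stopifnot(inherits(stats, "baseline_stats"))
  stats$I_b + multiplier * stats$sigma_b
}

#' Extract particle events from a time scan
#'
#' Maximal runs of dwells strictly above the threshold become one event
#' each (ties fall to baseline). Runs separated by at most `gap_tolerance`
#' sub-threshold dwells are merged — at microsecond dwell times a single
#' particle's pulse spans several dwells and can dip below threshold
#' mid-event at low intensity. Integrated counts are baseline-corrected by
#' I_b per member dwell, so longer events receive proportionally larger
#' corrections; for merged events the bridged gap dwells are members too.
#'
#' @param scan A [timescan()].
#' @param stats Baseline statistics computed from this scan.
#' @param gap_tolerance Maximum sub-threshold gap (in dwells) bridged when
#'   merging adjacent runs (default 0: no merging).
#' @return A tibble of class `particle_events` with columns `start_dwell`,
#'   `n_dwells`, `integrated_counts`, `peak_counts`, sorted by
#'   `start_dwell`; the baseline statistics travel as attribute `baseline`.
#' @export
detect_events <- function(scan, stats = estimate_baseline(scan),
                          gap_tolerance = 0) {
  stopifnot(inherits(scan, "timescan"), inherits(stats, "baseline_stats"))
  x <- as.numeric(scan$counts)
  above <- x > stats$I_thresh
  ev <- tibble::tibble(start_dwell = integer(), n_dwells = integer(),
                       integrated_counts = numeric(), peak_counts = integer())
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (gap_tolerance > 0) {
      # flip short interior FALSE runs bridging two events
      interior <- which(!r$values & r$lengths <= gap_tolerance &
                          seq_along(r$values) > 1 &
                          seq_along(r$values) < length(r$values))
      for (i in interior) above[starts[i]:ends[i]] <- TRUE
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
    }
    keep <- r$values
    s <- starts[keep]
    e <- ends[keep]
    ev <- tibble::tibble(
      start_dwell = as.integer(s),
      n_dwells = as.integer(e - s + 1L),
      integrated_counts = purrr::map2_dbl(s, e, function(a, b) {
        sum(x[a:b] - stats$I_b)
      }),
      peak_counts = purrr::map2_int(s, e, function(a, b) {
        as.integer(max(x[a:b]))
      })
    )
  }
  structure(ev, baseline = stats,
            meta = attr(scan, "meta", exact = TRUE),
            class = c("particle_events", class(tibble::tibble())))
}

#' Event-coincidence (dwell-occupancy) check
#'
#' At high particle number concentrations two particles can land in one
#' event, biasing both size and number concentration; suspensions should be
#' diluted so only a small fraction of dwells is particle-occupied.
#'
#' @param events Events from [detect_events()] on `scan`.
#' @param scan The [timescan()] the events were detected in.
#' @param limit Occupancy fraction above which the flag is raised
#'   (default 0.05).
#' @return A one-row tibble: `occupancy` (fraction of dwells inside events),
#'   `flag` (logical), `limit`.
#' @export
coincidence_check <- function(events, scan, limit = 0.05) {
  stopifnot(inherits(scan, "timescan"))
  occ <- if (nrow(events) == 0) 0 else sum(events$n_dwells) / nrow(scan)
  tibble::tibble(occupancy = occ, flag = occ > limit, limit = limit)
}
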