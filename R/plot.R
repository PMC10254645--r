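#' Plot a time scan
#'
#' Counts per dwell against acquisition time, optionally with the baseline
#' and detection threshold overlaid.
#'
#' @param object A [timescan()].
#' @param stats Optional `baseline_stats`; when supplied, I_b and I_thresh
#'   are drawn as horizontal lines.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timescan
#' @export
autoplot.timescan <- function(object, stats = NULL, ...) {
  m <- scan_meta(object)
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       time_s = (.data$dwell - 1) * m$dwell_time)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$counts)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "counts per dwell",
                  title = m$sample_id,
                  subtitle = sprintf("%s, dwell %g s", m$isotope_label,
                                     m$dwell_time)) +
    ggplot2::theme_minimal()
  if (!is.null(stats)) {
    p <- p +
      ggplot2::geom_hline(yintercept = stats$I_b, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = stats$I_thresh, colour = "firebrick",
                          linetype = "dashed")
  }
  p
}

lognormal_curve <- function(x, median_nm, gsd, weight, n, binwidth) {
  weight * n * binwidth * dlnorm(x, log(median_nm), log(gsd))
}

#' Plot a fitted size distribution
#'
#' Histogram of event diameters with the fitted lognormal density scaled to
#' the counts.
#'
#' @param object A `size_distribution` from [fit_lognormal()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  h <- object$histogram
  bw <- mean(h$bin_right - h$bin_left)
  xs <- seq(min(h$bin_left), max(h$bin_right), length.out = 300)
  curve <- tibble::tibble(
    x = xs,
    y = lognormal_curve(xs, object$lognormal_median, object$lognormal_gsd,
                        1, object$n, bw))
  ggplot2::ggplot() +
    ggplot2::geom_col(data = h,
                      ggplot2::aes((.data$bin_left + .data$bin_right) / 2,
                                   .data$count),
                      width = bw, fill = "grey70", colour = "grey40") +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$x, .data$y),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "diameter (nm)", y = "particle count",
                  subtitle = sprintf("median %.1f nm, gsd %.2f (n = %d)",
                                     object$lognormal_median,
                                     object$lognormal_gsd, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a mixture fit
#'
#' Histogram of the diameters with each fitted lognormal component and
#' their sum.
#'
#' @param object A `mixture_fit` from [fit_mixture()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, ...) {
  d <- object$diameters
  h <- graphics::hist(d, breaks = "FD", plot = FALSE)
  bw <- mean(diff(h$breaks))
  hd <- tibble::tibble(mid = h$mids, count = h$counts)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 300)
  comp <- purrr::imap_dfr(seq_len(nrow(object$components)), function(i, ...) {
    co <- object$components[i, ]
    tibble::tibble(x = xs, component = factor(i),
                   y = lognormal_curve(xs, co$median_nm, co$gsd, co$weight,
                                       object$n, bw))
  })
  ggplot2::ggplot() +
    ggplot2::geom_col(data = hd, ggplot2::aes(.data$mid, .data$count),
                      width = bw, fill = "grey70", colour = "grey40") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(.data$x, .data$y,
                                    colour = .data$component),
                       linewidth = 0.8) +
    ggplot2::labs(x = "diameter (nm)", y = "particle count",
                  subtitle = sprintf("k = %d (BIC)", object$k)) +
    ggplot2::theme_minimal()
}
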