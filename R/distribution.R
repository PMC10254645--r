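#' Fit a lognormal size distribution
#'
#' Maximum likelihood on the log scale, binning-free: the median diameter
#' is `exp(mean(log d))` and the geometric standard deviation
#' `exp(sd_mle(log d))`. A histogram (Freedman-Diaconis bins by default) is
#' attached for reporting and plotting only; it plays no part in the fit.
#'
#' @param diameters Particle diameters, nm (all > 0).
#' @param breaks Histogram break specification passed to
#'   [graphics::hist()] (default `"FD"`).
#' @return A `size_distribution` object: `diameters`, `n`,
#'   `lognormal_median` (nm), `lognormal_gsd`, `histogram` (tibble of
#'   `bin_left`, `bin_right`, `count`), `fit_method`.
#' @export
#' @examples
#' fit_lognormal(rlnorm(500, log(59), log(1.3)))
fit_lognormal <- function(diameters, breaks = "FD") {
  if (length(diameters) < 1) abort("Need at least one diameter.")
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    abort("Diameters must be finite and > 0 (nm).")
  }
  y <- log(diameters)
  mu <- mean(y)
  s <- sqrt(mean((y - mu)^2))  # MLE (n denominator); 0 when n = 1
  h <- graphics::hist(diameters, breaks = breaks, plot = FALSE)
  structure(
    list(diameters = as.numeric(diameters), n = length(diameters),
         lognormal_median = exp(mu), lognormal_gsd = exp(s),
         histogram = tibble::tibble(
           bin_left = utils::head(h$breaks, -1),
           bin_right = utils::tail(h$breaks, -1),
           count = h$counts),
         fit_method = "mle_log"),
    class = "size_distribution"
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "<size_distribution> n=%d: median %.3g nm, gsd %.3g (%s)\n",
    x$n, x$lognormal_median, x$lognormal_gsd, x$fit_method))
  invisible(x)
}

#' @method glance size_distribution
#' @export
glance.size_distribution <- function(x, ...) {
  tibble::tibble(n = x$n, lognormal_median = x$lognormal_median,
                 lognormal_gsd = x$lognormal_gsd, fit_method = x$fit_method)
}

#' @method tidy size_distribution
#' @export
tidy.size_distribution <- function(x, ...) x$histogram

# Gaussian mixture EM on log-diameters. Restarts are deterministic
# quantile splits, so the fit is reproducible without touching the RNG.
em_lognormal_2 <- function(y, n_restarts = 10, max_iter = 200, tol = 1e-8) {
  n <- length(y)
  best <- NULL
  sd_floor <- 1e-4
  cuts <- seq(0.15, 0.85, length.out = n_restarts)
  for (q in cuts) {
    split <- y <= quantile(y, q)
    if (sum(split) < 2 || sum(!split) < 2) next
    w <- mean(split)
    mu <- c(mean(y[split]), mean(y[!split]))
    s <- pmax(c(sd(y[split]), sd(y[!split])), sd_floor)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w * dnorm(y, mu[1], s[1])
      d2 <- (1 - w) * dnorm(y, mu[2], s[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      r <- d1 / tot
      ll <- sum(log(tot))
      w <- mean(r)
      if (w < 1e-6 || w > 1 - 1e-6) break
      mu <- c(sum(r * y) / sum(r), sum((1 - r) * y) / sum(1 - r))
      s <- pmax(c(sqrt(sum(r * (y - mu[1])^2) / sum(r)),
                  sqrt(sum((1 - r) * (y - mu[2])^2) / sum(1 - r))),
                sd_floor)
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, w = w, mu = mu, s = s)
    }
  }
  best
}

#' Fit a one- or two-component lognormal mixture
#'
#' Operationalises agglomerate detection: a second, heavier size mode
#' appearing in an aged suspension. Fits k = 1 and (when enough events are
#' available) k = 2 lognormal mixtures on the log scale by EM with
#' deterministic quantile-split restarts, then selects k by the Bayesian
#' information criterion — parsimonious at the few hundred events a typical
#' acquisition yields.
#'
#' @param diameters Particle diameters, nm.
#' @param max_k Maximum number of components considered (1 or 2).
#' @param min_n Minimum sample size before k = 2 is entertained
#'   (default 50).
#' @param n_restarts EM restarts (default 10).
#' @return A `mixture_fit`: `k`, `components` (tibble of `median_nm`,
#'   `gsd`, `weight`, sorted by median), `bic` (named vector over k),
#'   `note`.
#' @export
fit_mixture <- function(diameters, max_k = 2, min_n = 50, n_restarts = 10) {
  if (length(diameters) < 2) abort("Need at least two diameters.")
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    abort("Diameters must be finite and > 0 (nm).")
  }
  y <- log(diameters)
  n <- length(y)
  mu1 <- mean(y)
  s1 <- max(sqrt(mean((y - mu1)^2)), 1e-12)
  ll1 <- sum(dnorm(y, mu1, s1, log = TRUE))
  bic <- c(`1` = -2 * ll1 + 2 * log(n))
  note <- NA_character_

  fit2 <- NULL
  if (max_k >= 2) {
    if (n < min_n) {
      note <- sprintf(
        "n = %d below min_n = %d; two-component fit not attempted.", n, min_n)
    } else {
      fit2 <- em_lognormal_2(y, n_restarts = n_restarts)
      if (!is.null(fit2)) bic[["2"]] <- -2 * fit2$ll + 5 * log(n)
    }
  }

  if (!is.null(fit2) && bic[["2"]] < bic[["1"]]) {
    ord <- order(fit2$mu)
    comp <- tibble::tibble(
      median_nm = exp(fit2$mu[ord]),
      gsd = exp(fit2$s[ord]),
      weight = c(fit2$w, 1 - fit2$w)[ord])
    k <- 2L
  } else {
    comp <- tibble::tibble(median_nm = exp(mu1), gsd = exp(s1), weight = 1)
    k <- 1L
  }
  structure(
    list(k = k, components = comp, bic = bic, n = n, note = note,
         diameters = as.numeric(diameters)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d (n = %d)\n", x$k, x$n))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  mode %d: median %.3g nm, gsd %.3g, weight %.2f\n", i,
                x$components$median_nm[i], x$components$gsd[i],
                x$components$weight[i]))
  }
  if (!is.na(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = 1)
}

#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n,
                 bic_1 = x$bic[["1"]],
                 bic_2 = if ("2" %in% names(x$bic)) x$bic[["2"]] else NA_real_,
                 note = x$note)
}

#' Default thresholds for transformation classification
#'
#' Repository defaults calibrated so the endpoint scenario fixtures
#' classify correctly; every rule is exposed here.
#'
#' @param median_shift Relative increase of the aged median diameter above
#'   which agglomeration is called (default 0.15).
#' @param dissolved_rise Rise of the dissolved fraction of total analyte
#'   (aged minus fresh, absolute) above which partial dissolution is
#'   called (default 0.10, i.e. 10 percentage points).
#' @param count_ratio Aged/fresh event-count ratio below which partial
#'   dissolution is called at matched dilution (default 0.7).
#' @param heavy_mode_weight Minimum number weight of the heavier mixture
#'   mode for an agglomeration call (default 0.10).
#' @param min_mode_separation Minimum ratio of component medians for the
#'   two-mode fit to count as a genuine agglomerate mode (default 1.5).
#' @param fast_count_ratio Aged/fresh event-count ratio below which — with
#'   a dominant dissolved fraction — fast dissolution is called
#'   (default 0.10).
#' @param fast_dissolved Minimum aged dissolved fraction for a fast
#'   dissolution call (default 0.50).
#' @param min_events Minimum aged event count for size-based evidence
#'   (median shift, mixture modes); with fewer events the sample median is
#'   too noisy to support a size claim (default 50).
#' @return A named list of thresholds.
#' @export
transformation_thresholds <- function(median_shift = 0.15,
                                      dissolved_rise = 0.10,
                                      count_ratio = 0.7,
                                      heavy_mode_weight = 0.10,
                                      min_mode_separation = 1.5,
                                      fast_count_ratio = 0.10,
                                      fast_dissolved = 0.50,
                                      min_events = 50) {
  as.list(environment())
}

#' Classify the transformation between a fresh and an aged suspension
#'
#' Applies the three-scenario interpretation of nanoparticle fate in a
#' growth medium: stability (size distribution and background unchanged),
#' partial or total dissolution (rising dissolved fraction, falling event
#' count) and agglomeration (a second, heavier size mode or a strongly
#' increased median). Rules and thresholds are listed under
#' [transformation_thresholds()].
#'
#' @param fresh,aged `sample_result` objects from [analyze_timescan()] run
#'   with the same element and configuration.
#' @param thresholds A [transformation_thresholds()] list.
#' @return A `transformation_verdict`: `flags` (subset of `stable`,
#'   `partial_dissolution`, `agglomeration`, `fast_dissolution`),
#'   `evidence` (one-row tibble: median shift, dissolved-fraction change,
#'   event-count ratio, heavy-mode weight), `note`.
#' @export
classify_transformation <- function(fresh, aged,
                                    thresholds = transformation_thresholds()) {
  stopifnot(inherits(fresh, "sample_result"), inherits(aged, "sample_result"))
  th <- thresholds
  note <- character()

  median_shift <- if (is.finite(fresh$median_diameter_nm) &&
                      is.finite(aged$median_diameter_nm)) {
    aged$median_diameter_nm / fresh$median_diameter_nm - 1
  } else {
    note <- c(note, "median diameter unavailable for one input")
    NA_real_
  }
  dissolved_change <- if (is.finite(fresh$dissolved_fraction) &&
                          is.finite(aged$dissolved_fraction)) {
    aged$dissolved_fraction - fresh$dissolved_fraction
  } else {
    note <- c(note, "dissolved-fraction evidence missing")
    NA_real_
  }
  count_ratio <- if (fresh$n_events > 0) {
    aged$n_events / fresh$n_events
  } else {
    note <- c(note, "fresh run has no events; count ratio undefined")
    NA_real_
  }

  size_evidence_ok <- aged$n_events >= th$min_events &&
    fresh$n_events >= th$min_events
  heavy_weight <- 0
  mode_separation <- NA_real_
  mix <- NULL
  if (aged$n_events >= max(2, th$min_events)) {
    mix <- fit_mixture(aged$events$diameter_nm, min_n = th$min_events)
    if (mix$k == 2) {
      heavy_weight <- mix$components$weight[2]
      mode_separation <- mix$components$median_nm[2] /
        mix$components$median_nm[1]
    }
  }

  flags <- character()
  agglo_mode <- !is.null(mix) && mix$k == 2 &&
    heavy_weight >= th$heavy_mode_weight &&
    isTRUE(mode_separation >= th$min_mode_separation)
  agglo_median <- size_evidence_ok && isTRUE(median_shift > th$median_shift)
  if (agglo_mode || agglo_median) flags <- c(flags, "agglomeration")

  if (isTRUE(dissolved_change > th$dissolved_rise) ||
      isTRUE(count_ratio < th$count_ratio)) {
    flags <- c(flags, "partial_dissolution")
  }
  if (isTRUE(count_ratio < th$fast_count_ratio) &&
      isTRUE(aged$dissolved_fraction > th$fast_dissolved)) {
    flags <- c(flags, "fast_dissolution")
  }
  if (length(flags) == 0) {
    flags <- "stable"
    if (length(note) > 0) {
      note <- c(note, "insufficient evidence for any transformation call")
    }
  }

  structure(
    list(flags = flags,
         evidence = tibble::tibble(
           median_shift = median_shift,
           dissolved_change = dissolved_change,
           count_ratio = count_ratio,
           heavy_mode_weight = heavy_weight,
           mode_separation = mode_separation,
           n_events_fresh = fresh$n_events,
           n_events_aged = aged$n_events),
         mixture = mix,
         note = if (length(note)) paste(note, collapse = "; ")
                else NA_character_,
         thresholds = th),
    class = "transformation_verdict"
  )
}

#' @export
print.transformation_verdict <- function(x, ...) {
  cat("<transformation_verdict> ", paste(x$flags, collapse = " + "), "\n",
      sep = "")
  e <- x$evidence
  cat(sprintf(
    "  median shift %+.1f%%, dissolved change %+.1f pts, count ratio %.3g, heavy mode %.0f%%\n",
    100 * e$median_shift, 100 * e$dissolved_change, e$count_ratio,
    100 * e$heavy_mode_weight))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @method tidy transformation_verdict
#' @export
tidy.transformation_verdict <- function(x, ...) x$evidence

#' @method glance transformation_verdict
#' @export
glance.transformation_verdict <- function(x, ...) {
  tibble::tibble(verdict = paste(x$flags, collapse = "+"),
                 stable = "stable" %in% x$flags,
                 partial_dissolution = "partial_dissolution" %in% x$flags,
                 agglomeration = "agglomeration" %in% x$flags,
                 fast_dissolution = "fast_dissolution" %in% x$flags,
                 note = x$note)
}

#' One-way ANOVA across groups of replicate values
#'
#' Classical fixed-effects one-way analysis of variance, significant at
#' p < 0.05, as used to compare e.g. median diameters across treatments.
#'
#' @param groups Either a data frame with columns `group` and `value`, or a
#'   named list of numeric vectors.
#' @return A `group_comparison`: group labels, `F_statistic`, degrees of
#'   freedom, `p_value`, `significant` (at alpha = 0.05).
#' @export
#' @examples
#' compare_groups(list(a = c(59, 60, 58), b = c(61, 62, 60)))
compare_groups <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups))) {
      abort("Data-frame input needs columns `group` and `value`.")
    }
    dat <- tibble::tibble(group = as.character(groups$group),
                          value = as.numeric(groups$value))
  } else {
    if (is.null(names(groups))) abort("List input must be named by group.")
    dat <- purrr::imap_dfr(groups, function(v, nm) {
      tibble::tibble(group = nm, value = as.numeric(v))
    })
  }
  sizes <- table(dat$group)
  if (length(sizes) < 2) abort("Need at least two groups.")
  if (any(sizes < 2)) abort("Every group needs at least two values.")
  if (sd(dat$value) == 0) {
    abort("All values identical across all groups; ANOVA is degenerate.")
  }
  fit <- lm(value ~ group, data = dat)
  a <- anova(fit)
  f <- a$`F value`[1]
  p <- a$`Pr(>F)`[1]
  if (!is.finite(f)) {  # zero residual variance with non-zero separation
    f <- Inf
    p <- 0
  }
  structure(
    list(groups = names(sizes), F_statistic = f,
         df = unname(a$Df), p_value = p, significant = p < 0.05,
         alpha = 0.05, data = dat),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %d groups: F(%d, %d) = %.4g, p = %.4g (%s at alpha = %g)\n",
    length(x$groups), x$df[1], x$df[2], x$F_statistic, x$p_value,
    if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(n_groups = length(x$groups), F_statistic = x$F_statistic,
                 df_between = x$df[1], df_within = x$df[2],
                 p_value = x$p_value, significant = x$significant)
}

#' Particle recovery after filtration
#'
#' Percentage of the particle number concentration surviving a filtration
#' step, `100 * after / before`. Substantial losses on membranes with pore
#' sizes far above the particle diameter are common (agglomeration and
#' adsorption on the membrane), so this is reported before analysing
#' filtered suspensions.
#'
#' @param before,after Particle number concentrations (per litre),
#'   vectorised.
#' @return Recovery in percent.
#' @export
#' @examples
#' recovery_after_filtration(2.5e7, 1.1e7)  # 44%
recovery_after_filtration <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0)) {
    abort("`before` must be finite and > 0.")
  }
  if (any(!is.finite(after)) || any(after < 0)) {
    abort("`after` must be finite and >= 0.")
  }
  100 * after / before
}
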