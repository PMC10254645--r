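#' Fit an external ionic calibration line
#'
#' Ordinary least squares of instrument response (cps) on dissolved-analyte
#' concentration (µg/L), the usual external-calibration mechanics. The slope
#' converts concentrations to count rates and — combined with the sample
#' uptake rate and transport efficiency — event counts to particle mass.
#'
#' @param points A data frame with columns `concentration_ug_L` and
#'   `response_cps` (e.g. a 7-point series spanning 0–50 µg/L), or from
#'   [read_ionic_calibration()].
#' @param response_unit `"cps"` (default) or `"counts_per_dwell"`; the
#'   latter is divided by `dwell_time` so the fitted slope is always on the
#'   per-second basis used everywhere downstream.
#' @param dwell_time Dwell time in seconds, required when
#'   `response_unit = "counts_per_dwell"`.
#' @return An `ionic_calibration` object with fields `slope_s`
#'   (cps per µg/L), `intercept` (cps), `r_squared`, `points` and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' pts <- tibble::tibble(concentration_ug_L = 0:6 * 8,
#'                       response_cps = 1000 * (0:6 * 8) + 50)
#' fit_ionic_calibration(pts)
fit_ionic_calibration <- function(points,
                                  response_unit = c("cps", "counts_per_dwell"),
                                  dwell_time = NULL) {
  response_unit <- match.arg(response_unit)
  stopifnot(is.data.frame(points))
  need <- c("concentration_ug_L", "response_cps")
  if (response_unit == "counts_per_dwell") {
    need[2] <- "response_counts_per_dwell"
  }
  if (!all(need %in% names(points))) {
    abort(sprintf("`points` needs columns %s.", paste(need, collapse = ", ")))
  }
  conc <- points[[need[1]]]
  resp <- points[[need[2]]]
  if (any(!is.finite(conc)) || any(!is.finite(resp))) {
    abort("Calibration points must be finite.")
  }
  if (length(unique(conc)) < 2) {
    abort("Need at least 2 distinct concentrations for a calibration line.")
  }
  if (response_unit == "counts_per_dwell") {
    if (is.null(dwell_time) || dwell_time <= 0) {
      abort("`dwell_time` (s) is required for counts-per-dwell responses.")
    }
    resp <- resp / dwell_time
  }
  fit <- lm(resp ~ conc)
  structure(
    list(slope_s = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         points = tibble::tibble(concentration_ug_L = conc,
                                 response_cps = resp),
         fit = fit),
    class = "ionic_calibration"
  )
}

#' Assemble an ionic calibration from known instrument constants
#'
#' Convenience constructor for simulation studies where the response slope
#' is a stated parameter rather than a fitted quantity.
#'
#' @param slope_s Response slope, cps per (µg/L); must be > 0.
#' @param intercept Blank response, cps (default 0).
#' @return An `ionic_calibration` object (no underlying `lm`).
#' @export
ionic_calibration <- function(slope_s, intercept = 0) {
  if (!is.finite(slope_s) || slope_s <= 0) abort("`slope_s` must be > 0.")
  structure(
    list(slope_s = slope_s, intercept = intercept, r_squared = NA_real_,
         points = tibble::tibble(concentration_ug_L = numeric(),
                                 response_cps = numeric()),
         fit = NULL),
    class = "ionic_calibration"
  )
}

#' @export
print.ionic_calibration <- function(x, ...) {
  cat(sprintf("<ionic_calibration> slope %.6g cps/(ug/L), intercept %.6g cps",
              x$slope_s, x$intercept))
  if (is.finite(x$r_squared)) cat(sprintf(", r2=%.5f", x$r_squared))
  cat(sprintf(" (%d points)\n", nrow(x$points)))
  invisible(x)
}

#' @method tidy ionic_calibration
#' @export
tidy.ionic_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope_s),
                 unit = c("cps", "cps per (ug/L)"))
}

#' @method glance ionic_calibration
#' @export
glance.ionic_calibration <- function(x, ...) {
  tibble::tibble(slope_s = x$slope_s, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = nrow(x$points))
}

#' Sample uptake rate from gravimetric replicates
#'
#' The uptake (sample flow) rate is measured by weighing the water drawn by
#' the peristaltic pump over a timed interval, typically 2 min repeated
#' three times. Water density is taken as 1.000 g/mL.
#'
#' @param replicates Data frame with columns `mass_g` and `duration_s`, one
#'   row per replicate.
#' @return A `flow_rate` object: `Q_sam` in litres/second (plus `Q_mL_min`
#'   for readability) and the replicate table.
#' @export
#' @examples
#' measure_flow_rate(tibble::tibble(mass_g = c(0.7, 0.7, 0.7),
#'                                  duration_s = 120))
measure_flow_rate <- function(replicates) {
  stopifnot(is.data.frame(replicates))
  if (!all(c("mass_g", "duration_s") %in% names(replicates))) {
    abort("`replicates` needs columns `mass_g` and `duration_s`.")
  }
  if (nrow(replicates) < 1) abort("Need at least one replicate.")
  if (any(replicates$mass_g <= 0) || any(replicates$duration_s <= 0)) {
    abort("Masses and durations must be > 0.")
  }
  # g/s at 1.000 g/mL -> mL/s -> L/s
  q <- mean(replicates$mass_g / replicates$duration_s) / 1000
  structure(
    list(Q_sam = q, Q_mL_min = q * 1000 * 60,
         replicate_masses = tibble::as_tibble(replicates)),
    class = "flow_rate"
  )
}

#' Flow rate from a known uptake value
#'
#' @param Q_sam Uptake rate in litres per second.
#' @return A `flow_rate` object.
#' @export
flow_rate <- function(Q_sam) {
  if (!is.finite(Q_sam) || Q_sam <= 0) abort("`Q_sam` must be > 0 (L/s).")
  structure(list(Q_sam = Q_sam, Q_mL_min = Q_sam * 6e4,
                 replicate_masses = tibble::tibble(mass_g = numeric(),
                                                   duration_s = numeric())),
            class = "flow_rate")
}

#' @export
print.flow_rate <- function(x, ...) {
  cat(sprintf("<flow_rate> Q_sam = %.4g L/s (%.3g mL/min)\n",
              x$Q_sam, x$Q_mL_min))
  invisible(x)
}

#' Transport efficiency by the particle-size method
#'
#' A nanoparticle standard of known diameter and density (typically 50 nm
#' gold) ties the ionic response curve to single-particle signals. With the
#' ionic slope s (cps per µg/L), uptake rate Q_sam (L/s) and transport
#' efficiency eta, a dissolved standard at C µg/L delivers C*Q_sam*eta µg/s
#' to the plasma and reads s*C cps, so the instrument counts
#' s/(Q_sam*eta) counts per µg reaching the plasma. A reference particle of
#' known mass m_ref therefore integrates to I = m_ref*s/(Q_sam*eta) counts,
#' giving
#'
#'   eta = m_ref * s / (I_ref_mean * Q_sam)
#'
#' with I_ref_mean the mean integrated counts per detected reference event.
#'
#' @param ref_events Events ([detect_events()]) from a reference-standard
#'   run.
#' @param d_ref Nominal reference diameter, nm.
#' @param rho_ref Reference particle density, g/cm3 (19.30 for gold).
#' @param cal An `ionic_calibration`.
#' @param flow A `flow_rate`.
#' @param mass_fraction Analyte mass fraction of the reference particle
#'   (default 1).
#' @return A `transport_efficiency` object: `eta_neb` in (0, 1], `method`,
#'   reference details, and `K_intr = eta_neb * Q_sam` (L/s).
#' @export
transport_efficiency_particle_size <- function(ref_events, d_ref, rho_ref,
                                               cal, flow,
                                               mass_fraction = 1) {
  stopifnot(inherits(cal, "ionic_calibration"), inherits(flow, "flow_rate"))
  if (d_ref <= 0 || rho_ref <= 0) abort("`d_ref` and `rho_ref` must be > 0.")
  if (cal$slope_s <= 0) abort("Calibration slope must be > 0.")
  if (nrow(ref_events) == 0) abort("No reference events to average.")
  if (nrow(ref_events) < 50) {
    warn(sprintf(
      "Only %d reference events; >= 50 are recommended for a stable transport efficiency.",
      nrow(ref_events)))
  }
  elem_ref <- element_params(density_rho = rho_ref,
                             mass_fraction_X = mass_fraction)
  m_ref <- diameter_to_mass(d_ref, elem_ref)        # ug of analyte
  i_mean <- mean(ref_events$integrated_counts)
  eta <- m_ref * cal$slope_s / (i_mean * flow$Q_sam)
  if (!is.finite(eta) || eta <= 0 || eta > 1) {
    abort(sprintf(
      "Computed transport efficiency %.4g is outside (0, 1]; calibration, flow rate and reference run are inconsistent.",
      eta))
  }
  transport_efficiency(eta, flow,
                       method = "particle_size",
                       reference = list(d_ref_nm = d_ref,
                                        rho_ref = rho_ref,
                                        mean_event_counts = i_mean,
                                        n_events = nrow(ref_events)))
}

#' Transport efficiency from a known value
#'
#' @param eta_neb Nebulisation/transport efficiency, in (0, 1].
#' @param flow Optional `flow_rate`, used to attach `K_intr = eta * Q_sam`.
#' @param method Provenance label.
#' @param reference Optional reference-standard details.
#' @return A `transport_efficiency` object.
#' @export
transport_efficiency <- function(eta_neb, flow = NULL, method = "assumed",
                                 reference = NULL) {
  if (!is.finite(eta_neb) || eta_neb <= 0 || eta_neb > 1) {
    abort("`eta_neb` must lie in (0, 1].")
  }
  structure(
    list(eta_neb = eta_neb,
         K_intr = if (!is.null(flow)) eta_neb * flow$Q_sam else NA_real_,
         method = method, reference = reference),
    class = "transport_efficiency"
  )
}

#' @export
print.transport_efficiency <- function(x, ...) {
  cat(sprintf("<transport_efficiency> eta = %.4g (%.2f%%), method: %s\n",
              x$eta_neb, 100 * x$eta_neb, x$method))
  if (is.finite(x$K_intr)) cat(sprintf("  K_intr = %.4g L/s\n", x$K_intr))
  invisible(x)
}
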