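#' Analyte mass of a particle event
#'
#' With ionic slope s (cps per µg/L), uptake rate Q_sam (L/s) and transport
#' efficiency eta, the instrument registers s/(Q_sam * eta) counts per µg
#' of analyte reaching the plasma (see
#' [transport_efficiency_particle_size()] for the derivation), so an event
#' integrating to I baseline-corrected counts carries
#' m = I * Q_sam * eta / s micrograms. The ionic intercept is a blank count
#' *rate* and is already removed with the baseline, so only the slope
#' enters here.
#'
#' @param integrated_counts Baseline-corrected integrated counts, one value
#'   per event (vectorised). Also accepts an event tibble from
#'   [detect_events()].
#' @param cal An `ionic_calibration`.
#' @param flow A `flow_rate`.
#' @param eta A `transport_efficiency`.
#' @return Analyte mass per event, micrograms.
#' @export
event_mass <- function(integrated_counts, cal, flow, eta) {
  stopifnot(inherits(cal, "ionic_calibration"), inherits(flow, "flow_rate"),
            inherits(eta, "transport_efficiency"))
  if (is.data.frame(integrated_counts)) {
    integrated_counts <- integrated_counts$integrated_counts
  }
  if (cal$slope_s <= 0) abort("Calibration slope must be > 0.")
  if (any(integrated_counts < 0, na.rm = TRUE)) {
    abort("Integrated counts must be >= 0.")
  }
  integrated_counts * flow$Q_sam * eta$eta_neb / cal$slope_s
}

#' Attach mass and diameter to detected events
#'
#' @param events Events from [detect_events()].
#' @param cal,flow,eta Calibration objects (see [event_mass()]).
#' @param elem An [element_params()].
#' @return The event tibble with added `mass_ug`, `mass_fg` and
#'   `diameter_nm` columns.
#' @export
quantify_events <- function(events, cal, flow, eta, elem = element_params()) {
  m <- event_mass(events, cal, flow, eta)
  dplyr::mutate(events,
                mass_ug = m,
                mass_fg = m * 1e9,
                diameter_nm = mass_to_diameter(m, elem))
}

#' Particle number concentration from an event count
#'
#' Each detected event is one particle that survived nebulisation, so the
#' analysed suspension holds
#' `N = n_events / (eta * Q_sam * total_time)` particles per litre;
#' multiplying by the dilution factor gives the concentration in the
#' original extract, and scaling by extract volume over tissue mass gives
#' particles per gram of digested tissue.
#'
#' @param n_events Number of detected events.
#' @param flow A `flow_rate`.
#' @param eta A `transport_efficiency`.
#' @param meta An [acquisition_meta()] (acquisition time, dilution,
#'   extract volume, tissue mass).
#' @return One-row tibble: `number_per_L` (extract basis, dilution
#'   applied) and `number_per_gram`.
#' @export
#' @examples
#' number_concentration(300, flow_rate(5.8333e-6),
#'                      transport_efficiency(0.075), acquisition_meta())
number_concentration <- function(n_events, flow, eta, meta) {
  stopifnot(inherits(flow, "flow_rate"), inherits(eta, "transport_efficiency"),
            inherits(meta, "acquisition_meta"))
  if (meta$total_time <= 0) abort("`total_time` must be > 0.")
  per_l <- n_events / (eta$eta_neb * flow$Q_sam * meta$total_time) *
    meta$dilution_factor
  tibble::tibble(number_per_L = per_l,
                 number_per_gram = per_l * meta$extract_volume /
                   meta$tissue_mass)
}

#' Dissolved-analyte concentration from the baseline
#'
#' The baseline carries the dissolved fraction of the element: its mean
#' count per dwell, expressed per second and blank-corrected by the
#' calibration intercept, divides by the ionic slope to give µg/L in the
#' analysed suspension. Negative results floor at zero with a warning.
#'
#' @param stats Baseline statistics from [estimate_baseline()].
#' @param cal An `ionic_calibration`.
#' @param meta An [acquisition_meta()] (for the dwell time).
#' @return Dissolved concentration in the analysed suspension, µg/L.
#' @export
dissolved_concentration <- function(stats, cal, meta) {
  stopifnot(inherits(stats, "baseline_stats"),
            inherits(cal, "ionic_calibration"),
            inherits(meta, "acquisition_meta"))
  if (cal$slope_s <= 0) abort("Calibration slope must be > 0.")
  conc <- (stats$I_b / meta$dwell_time - cal$intercept) / cal$slope_s
  if (conc < 0) {
    warn("Dissolved concentration below blank; flooring at 0.")
    conc <- 0
  }
  conc
}

#' Detection-efficiency product from a dissolved standard
#'
#' The counts-per-mass response of the instrument factorises into an
#' instrument-dependent detection efficiency K_ICPMS and the element factor
#' K_M = A * N_Av / M_M; only their product matters for sizing, and it is
#' measurable from a dissolved standard:
#' `K_ICPMS * K_M = R / (K_intr * C_M)` with R the counted ions per second,
#' K_intr = eta * Q_sam the sample-introduction factor, and C_M the
#' standard's concentration. Returned here in counts per µg.
#'
#' @param R Ions counted per second for the standard (cps).
#' @param C_M Standard concentration, µg/L.
#' @param K_intr eta * Q_sam, L/s.
#' @return Counts per µg of analyte.
#' @export
detection_efficiency_product <- function(R, C_M, K_intr) {
  if (any(c(R, C_M, K_intr) <= 0) || any(!is.finite(c(R, C_M, K_intr)))) {
    abort("`R`, `C_M` and `K_intr` must all be finite and > 0.")
  }
  R / (K_intr * C_M)
}

#' Size detection limit
#'
#' Smallest spherical-equivalent diameter distinguishable from the
#' background, from the background standard deviation and the instrument's
#' counts-per-mass response:
#'
#'   LOD_size = ( 6 * 3 sigma_B / (pi * rho * X_NP * K_ICPMS * K_M) )^(1/3)
#'
#' The 3-sigma numerator is the conventional decision criterion for a
#' detection limit and is deliberately smaller than the 5-sigma event
#' threshold used for particle/dissolved discrimination; the `multiplier`
#' argument exposes it. `sigma_B` must be on the same basis as the event
#' integrals it is compared against (see [analyze_timescan()], which scales
#' the per-dwell baseline SD by the square root of the pulse length).
#'
#' @param sigma_B Background standard deviation, counts.
#' @param elem An [element_params()].
#' @param K_product Detection-efficiency product, counts per µg
#'   (see [detection_efficiency_product()]).
#' @param multiplier Detection criterion in sigmas (default 3).
#' @return Size detection limit, nm.
#' @export
#' @examples
#' size_lod(1, element_params(), 2.286e9)  # ~68 nm
size_lod <- function(sigma_B, elem = element_params(), K_product,
                     multiplier = 3) {
  stopifnot(inherits(elem, "element_params"))
  if (any(c(sigma_B, K_product, multiplier) <= 0)) {
    abort("`sigma_B`, `K_product` and `multiplier` must be > 0.")
  }
  # counts / (counts/ug) -> ug; * 1e-6 -> g; / (rho X) -> cm3; -> cm -> nm
  (6 * multiplier * sigma_B * 1e-6 /
     (pi * elem$density_rho * elem$mass_fraction_X * K_product))^(1 / 3) * 1e7
}

#' Signal-to-noise ratio across reaction-gas flows
#'
#' Cell-gas optimisation: for each candidate gas flow, the analyte response
#' of a dissolved standard is divided by the noise of a particle-free
#' matrix trace at that flow (delta, the per-second standard deviation of
#' the matrix signal). The flow maximising S/N in the most matrix-rich
#' condition is the one to retain.
#'
#' @param analyte_response Named numeric vector of analyte responses (cps),
#'   one per gas flow; names are the flow labels (e.g. mL/min values).
#' @param matrix_traces Named list of particle-free [timescan()]s, same
#'   names as `analyte_response`.
#' @return A tibble (`gas_flow`, `response_cps`, `delta_cps`, `snr`,
#'   `undefined`) with the argmax flow as attribute `best_flow`; flows with
#'   zero noise are flagged `undefined` and excluded from the argmax.
#' @export
signal_to_noise <- function(analyte_response, matrix_traces) {
  flows <- names(analyte_response)
  if (is.null(flows) || !setequal(flows, names(matrix_traces))) {
    abort("`analyte_response` and `matrix_traces` must share the same names.")
  }
  res <- purrr::map_dfr(flows, function(f) {
    ts <- matrix_traces[[f]]
    stopifnot(inherits(ts, "timescan"))
    delta <- sd(ts$counts) / scan_meta(ts)$dwell_time
    tibble::tibble(gas_flow = f,
                   response_cps = unname(analyte_response[f]),
                   delta_cps = delta,
                   snr = ifelse(delta > 0,
                                unname(analyte_response[f]) / delta, NA_real_),
                   undefined = delta <= 0)
  })
  ok <- !res$undefined
  attr(res, "best_flow") <- if (any(ok)) {
    res$gas_flow[ok][which.max(res$snr[ok])]
  } else {
    NA_character_
  }
  res
}

#' Full per-sample reduction of a time scan
#'
#' Runs the whole chain on one trace: baseline and threshold, event
#' detection, coincidence check, per-event mass and diameter, number and
#' mass concentrations (per litre of extract and per gram of tissue),
#' dissolved concentration, size detection limit and the lognormal size
#' distribution.
#'
#' @param scan A [timescan()].
#' @param cal,flow,eta Calibration objects (see [event_mass()]).
#' @param elem An [element_params()].
#' @param gap_tolerance Passed to [detect_events()]. The pipeline default
#'   is 1 dwell: at microsecond dwell times the flanks of a multi-dwell
#'   pulse cross the threshold through a noisy transition zone, and a
#'   single sub-threshold dip there would otherwise split one particle
#'   into a main event plus a tiny satellite.
#' @param lod_pulse_dwells Number of dwells a typical pulse spans; the LOD
#'   background SD is the per-dwell baseline SD scaled by its square root,
#'   putting sigma_B on the event-integral basis (default 3).
#' @param threshold_multiplier Event-threshold multiplier (default 5).
#' @param lod_multiplier Detection-limit criterion in sigmas (default 3).
#' @return A `sample_result` object; see [glance.sample_result()] for the
#'   one-row summary. Fields include the quantified `events` tibble,
#'   `baseline`, `occupancy`, `n_events`, `number_per_L`,
#'   `number_per_gram`, `particulate_ug_L`, `mass_per_gram_ng`,
#'   `dissolved_ug_L`, `dissolved_fraction`, `lod_nm`,
#'   `median_diameter_nm` and the fitted `size_distribution`.
#' @export
analyze_timescan <- function(scan, cal, flow, eta, elem = element_params(),
                             gap_tolerance = 1, lod_pulse_dwells = 3,
                             threshold_multiplier = 5, lod_multiplier = 3) {
  meta <- scan_meta(scan)
  stats <- estimate_baseline(scan, multiplier = threshold_multiplier)
  events <- detect_events(scan, stats, gap_tolerance = gap_tolerance)
  coin <- coincidence_check(events, scan)
  events <- quantify_events(events, cal, flow, eta, elem)

  nconc <- number_concentration(nrow(events), flow, eta, meta)
  diss <- dissolved_concentration(stats, cal, meta)
  # particulate mass per litre of extract: sum of event masses over the
  # analysed volume, scaled by dilution
  analysed_volume <- eta$eta_neb * flow$Q_sam * meta$total_time
  part_ug_l <- sum(events$mass_ug) / analysed_volume * meta$dilution_factor
  diss_extract <- diss * meta$dilution_factor
  total_fe <- part_ug_l + diss_extract
  mass_per_gram_ng <- part_ug_l * meta$extract_volume / meta$tissue_mass * 1e3

  k_product <- detection_efficiency_product(
    R = cal$slope_s, C_M = 1, K_intr = eta$eta_neb * flow$Q_sam)
  lod <- size_lod(max(stats$sigma_b, .Machine$double.eps) *
                    sqrt(lod_pulse_dwells),
                  elem, k_product, multiplier = lod_multiplier)

  dist <- if (nrow(events) > 0 && all(events$diameter_nm > 0)) {
    fit_lognormal(events$diameter_nm)
  } else {
    NULL
  }

  structure(
    list(sample_id = meta$sample_id,
         meta = meta, baseline = stats, events = events,
         occupancy = coin$occupancy, coincidence_flag = coin$flag,
         n_events = nrow(events),
         number_per_L = nconc$number_per_L,
         number_per_gram = nconc$number_per_gram,
         particulate_ug_L = part_ug_l,
         mass_per_gram_ng = mass_per_gram_ng,
         dissolved_ug_L = diss_extract,
         dissolved_fraction = if (total_fe > 0) diss_extract / total_fe
                              else NA_real_,
         lod_nm = lod,
         median_diameter_nm = if (!is.null(dist)) dist$lognormal_median
                              else NA_real_,
         size_distribution = dist),
    class = "sample_result"
  )
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("<sample_result> %s\n", x$sample_id))
  cat(sprintf("  %d events (occupancy %.3g%%%s), I_thresh %.4g counts/dwell\n",
              x$n_events, 100 * x$occupancy,
              if (x$coincidence_flag) ", COINCIDENCE FLAG" else "",
              x$baseline$I_thresh))
  cat(sprintf("  number conc: %.4g /L extract (%.4g /g tissue)\n",
              x$number_per_L, x$number_per_gram))
  cat(sprintf("  particulate: %.4g ug/L (%.4g ng/g); dissolved %.4g ug/L (%.1f%% of Fe)\n",
              x$particulate_ug_L, x$mass_per_gram_ng, x$dissolved_ug_L,
              100 * x$dissolved_fraction))
  cat(sprintf("  median diameter %.3g nm; size LOD %.3g nm\n",
              x$median_diameter_nm, x$lod_nm))
  invisible(x)
}

#' One-row summary of a sample result
#'
#' @param x A `sample_result` from [analyze_timescan()].
#' @param ... Unused.
#' @return A one-row tibble of the reported quantities.
#' @method glance sample_result
#' @export
glance.sample_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, n_events = x$n_events,
    number_per_L = x$number_per_L, number_per_gram = x$number_per_gram,
    particulate_ug_L = x$particulate_ug_L,
    mass_per_gram_ng = x$mass_per_gram_ng,
    dissolved_ug_L = x$dissolved_ug_L,
    dissolved_fraction = x$dissolved_fraction,
    median_diameter_nm = x$median_diameter_nm, lod_nm = x$lod_nm,
    occupancy = x$occupancy, I_thresh = x$baseline$I_thresh
  )
}

#' @method tidy sample_result
#' @export
tidy.sample_result <- function(x, ...) x$events
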