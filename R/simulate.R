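#' Configuration for the synthetic time-scan generator
#'
#' The generator emulates the statistical structure the detection and
#' fitting stages assume: Poisson particle arrivals at a target number
#' concentration, lognormally distributed diameters (optionally a
#' two-component mixture for agglomerate populations), pulses spread over
#' several consecutive dwells, and a dissolved-analyte baseline with shot
#' noise.
#'
#' @param number_concentration Particles per litre of the analysed
#'   suspension.
#' @param size_median Median diameter, nm.
#' @param size_gsd Geometric standard deviation (>= 1; exactly 1 is
#'   monodisperse).
#' @param second_mode Optional list `(median, gsd, fraction)` describing an
#'   agglomerate mode holding `fraction` of the particle number.
#' @param dissolved_concentration Dissolved analyte, µg/L.
#' @param uptake_rate Sample uptake rate Q_sam, L/s (default 5.8333e-6,
#'   i.e. 0.35 mL/min).
#' @param transport_efficiency Nebulisation/transport efficiency eta in
#'   (0, 1] (default 0.075).
#' @param ionic_slope Ionic response slope, cps per (µg/L) (default 1e6).
#' @param pulse_width Full width at half maximum of the Gaussian event
#'   pulse, seconds (default 3e-4, i.e. ~3 dwells at 100 µs).
#' @param baseline_noise `"poisson"` (counting statistics, default) or
#'   `"gaussian(<sd>)"` with `<sd>` in counts per dwell.
#' @param seed Optional integer seed set before drawing.
#' @return A `simulation_config` object (named list).
#' @export
simulation_config <- function(number_concentration = 7e6,
                              size_median = 59,
                              size_gsd = 1.3,
                              second_mode = NULL,
                              dissolved_concentration = 0.5,
                              uptake_rate = 0.35e-3 / 60,
                              transport_efficiency = 0.075,
                              ionic_slope = 1e6,
                              pulse_width = 3e-4,
                              baseline_noise = "poisson",
                              seed = NULL) {
  if (number_concentration < 0 || dissolved_concentration < 0) {
    abort("Concentrations must be >= 0.")
  }
  if (size_median <= 0 || size_gsd < 1) {
    abort("`size_median` must be > 0 and `size_gsd` >= 1.")
  }
  if (transport_efficiency <= 0 || transport_efficiency > 1) {
    abort("`transport_efficiency` must lie in (0, 1].")
  }
  if (uptake_rate <= 0 || ionic_slope <= 0 || pulse_width <= 0) {
    abort("`uptake_rate`, `ionic_slope` and `pulse_width` must be > 0.")
  }
  if (!is.null(second_mode)) {
    stopifnot(is.list(second_mode),
              all(c("median", "gsd", "fraction") %in% names(second_mode)))
    if (second_mode$median <= 0 || second_mode$gsd < 1 ||
        second_mode$fraction < 0 || second_mode$fraction > 1) {
      abort("`second_mode` must have median > 0, gsd >= 1, fraction in [0, 1].")
    }
  }
  parse_noise(baseline_noise)  # validate early
  structure(
    list(number_concentration = number_concentration,
         size_median = size_median, size_gsd = size_gsd,
         second_mode = second_mode,
         dissolved_concentration = dissolved_concentration,
         uptake_rate = uptake_rate,
         transport_efficiency = transport_efficiency,
         ionic_slope = ionic_slope, pulse_width = pulse_width,
         baseline_noise = baseline_noise, seed = seed),
    class = "simulation_config"
  )
}

parse_noise <- function(spec) {
  if (identical(spec, "poisson")) return(list(kind = "poisson"))
  m <- regmatches(spec, regexec("^gaussian\\(([0-9.eE+-]+)\\)$", spec))[[1]]
  if (length(m) == 2) {
    sd <- as.numeric(m[2])
    if (is.finite(sd) && sd >= 0) return(list(kind = "gaussian", sd = sd))
  }
  abort("`baseline_noise` must be \"poisson\" or \"gaussian(<sd>)\".")
}

draw_diameters <- function(n, cfg) {
  if (n == 0) {
    return(tibble::tibble(diameter_nm = numeric(), mode = integer()))
  }
  mode <- rep(1L, n)
  if (!is.null(cfg$second_mode)) {
    mode <- 1L + rbinom(n, 1L, cfg$second_mode$fraction)
  }
  d <- numeric(n)
  i1 <- mode == 1L
  d[i1] <- rlnorm(sum(i1), log(cfg$size_median), log(cfg$size_gsd))
  if (any(!i1)) {
    d[!i1] <- rlnorm(sum(!i1), log(cfg$second_mode$median),
                     log(cfg$second_mode$gsd))
  }
  tibble::tibble(diameter_nm = d, mode = mode)
}

#' Simulate a single-particle time scan with known ground truth
#'
#' Particle arrivals follow a Poisson process with expectation
#' `lambda = number_concentration * transport_efficiency * uptake_rate *
#' total_time`; arrival positions are uniform over the acquisition. Each
#' particle's analyte mass follows from its lognormal diameter via the
#' sphere model, its integrated signal is
#' `mass * ionic_slope / (uptake_rate * transport_efficiency)` counts,
#' spread over consecutive dwells by a discretised Gaussian pulse of FWHM
#' `pulse_width`. The dissolved baseline contributes
#' `ionic_slope * dissolved_concentration * dwell_time` mean counts per
#' dwell under the chosen noise model. Pulse and baseline are summed per
#' dwell and rounded once.
#'
#' @param cfg A [simulation_config()].
#' @param meta An [acquisition_meta()].
#' @param elem An [element_params()] (defaults to the nZVI / 56Fe core).
#' @return A list with elements `scan` (a [timescan()]) and `truth`
#'   (tibble: `particle`, `arrival_dwell`, `diameter_nm`, `mass_ug`,
#'   `mode`), the latter carrying attributes `dissolved_ug_L`,
#'   `expected_events` (lambda) and `particulate_ug_L` (the mass ledger
#'   on the analysed-suspension basis).
#' @export
simulate_timescan <- function(cfg, meta = acquisition_meta(),
                              elem = element_params()) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(meta, "acquisition_meta"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nd <- n_dwells(meta)
  lambda <- cfg$number_concentration * cfg$transport_efficiency *
    cfg$uptake_rate * meta$total_time
  sigma_dwell <- cfg$pulse_width / meta$dwell_time / (2 * sqrt(2 * log(2)))
  # a particle occupies roughly one pulse FWHM worth of dwells
  extent <- max(1, ceiling(cfg$pulse_width / meta$dwell_time))
  if (lambda * extent / nd > 0.05) {
    abort(sprintf(
      "Expected dwell occupancy %.1f%% exceeds 5%%: single-particle conditions are violated; dilute the simulated suspension.",
      100 * lambda * extent / nd))
  }
  n_p <- rpois(1, lambda)
  centres <- runif(n_p, 0, nd)
  sizes <- draw_diameters(n_p, cfg)
  mass_ug <- diameter_to_mass(sizes$diameter_nm, elem)
  i_tot <- mass_ug * cfg$ionic_slope /
    (cfg$uptake_rate * cfg$transport_efficiency)

  signal <- numeric(nd)
  half <- max(1, ceiling(4 * sigma_dwell))
  for (p in seq_len(n_p)) {
    c0 <- centres[p]
    lo <- max(1L, floor(c0) + 1L - half)
    hi <- min(nd, floor(c0) + 1L + half)
    k <- lo:hi
    if (sigma_dwell > 0) {
      frac <- pnorm(k, c0, sigma_dwell) - pnorm(k - 1, c0, sigma_dwell)
    } else {
      frac <- as.numeric(k == min(max(floor(c0) + 1L, 1L), nd))
    }
    s <- sum(frac)
    if (s > 0) signal[k] <- signal[k] + i_tot[p] * frac / s
  }

  mean_b <- cfg$ionic_slope * cfg$dissolved_concentration * meta$dwell_time
  noise <- parse_noise(cfg$baseline_noise)
  baseline <- switch(noise$kind,
    poisson = rpois(nd, mean_b),
    gaussian = rnorm(nd, mean_b, noise$sd)
  )
  counts <- pmax(0, round(signal + baseline))

  truth <- tibble::tibble(
    particle = seq_len(n_p),
    arrival_dwell = pmin(nd, pmax(1L, as.integer(floor(centres) + 1L))),
    diameter_nm = sizes$diameter_nm,
    mass_ug = mass_ug,
    mode = sizes$mode
  )
  attr(truth, "dissolved_ug_L") <- cfg$dissolved_concentration
  attr(truth, "expected_events") <- lambda
  attr(truth, "particulate_ug_L") <- sum(mass_ug) /
    (cfg$transport_efficiency * cfg$uptake_rate * meta$total_time)
  attr(truth, "config") <- cfg
  list(scan = timescan(counts, meta), truth = truth)
}

#' Simulate a reference-nanoparticle standard run
#'
#' A monodisperse (or narrow) population at a nominal diameter and density,
#' as used to calibrate transport efficiency by the particle-size method
#' (classically 50 nm gold, density 19.30 g/cm3).
#'
#' @param d_ref Nominal diameter, nm.
#' @param rho_ref Particle density, g/cm3.
#' @param cfg A [simulation_config()]; its `size_median` is replaced by
#'   `d_ref`, its `second_mode` dropped. Set `size_gsd = 1` for a strictly
#'   monodisperse standard.
#' @param meta An [acquisition_meta()].
#' @return As [simulate_timescan()].
#' @export
simulate_reference_standard <- function(d_ref, rho_ref = 19.30,
                                        cfg = simulation_config(size_gsd = 1),
                                        meta = acquisition_meta()) {
  if (d_ref <= 0) abort("`d_ref` must be > 0.")
  cfg$size_median <- d_ref
  cfg$second_mode <- NULL
  elem_ref <- element_params(density_rho = rho_ref, mass_fraction_X = 1)
  simulate_timescan(cfg, meta, elem_ref)
}

# Endpoint fixtures for the three fates of nanoparticles in growth media.
# Anchors: stable 59 -> 61 nm with negligible background; dissolution +
# agglomeration 55 -> pooled 81 nm with a heavy mode and elevated
# background; fast dissolution leaves < 20 events over a high baseline.
scenario_params <- function(scenario) {
  base <- list(number_concentration = 7e6, gsd = 1.3, dissolved = 0)
  switch(scenario,
    stable = list(
      fresh = list(median = 59, gsd = base$gsd, conc = base$number_concentration,
                   dissolved = base$dissolved, second = NULL),
      aged = list(median = 61, gsd = base$gsd, conc = base$number_concentration,
                  dissolved = base$dissolved, second = NULL)
    ),
    dissolution_agglomeration = {
      heavy <- list(median = 150, gsd = 1.25)
      # number fraction of the heavy mode such that the pooled median is 81 nm
      f <- uniroot(function(f) {
        (1 - f) * plnorm(81, log(55), log(1.3)) +
          f * plnorm(81, log(heavy$median), log(heavy$gsd)) - 0.5
      }, c(1e-6, 1 - 1e-6))$root
      list(
        fresh = list(median = 55, gsd = base$gsd,
                     conc = base$number_concentration,
                     dissolved = base$dissolved, second = NULL),
        aged = list(median = 55, gsd = base$gsd,
                    conc = 0.6 * base$number_concentration,
                    dissolved = 0.3,
                    second = list(median = heavy$median, gsd = heavy$gsd,
                                  fraction = f))
      )
    },
    fast_dissolution = list(
      fresh = list(median = 55, gsd = base$gsd, conc = base$number_concentration,
                   dissolved = base$dissolved, second = NULL),
      aged = list(median = 55, gsd = base$gsd, conc = 1.2e5,
                  dissolved = 0.5, second = NULL)
    ),
    abort(sprintf(
      "Unknown scenario \"%s\"; use \"stable\", \"dissolution_agglomeration\" or \"fast_dissolution\".",
      scenario))
  )
}

#' Generate a fresh/aged scenario fixture
#'
#' Emulates the three fates of nanoparticle suspensions incubated in a
#' growth medium: `"stable"` (median drifts 59 to 61 nm, negligible
#' dissolved background), `"dissolution_agglomeration"` (fresh 55 nm single
#' mode; aged keeps a reduced primary mode plus an agglomerate mode so the
#' pooled median is 81 nm, over an elevated dissolved background) and
#' `"fast_dissolution"` (aged trace with under 20 events over a high
#' dissolved baseline).
#'
#' @param scenario One of `"stable"`, `"dissolution_agglomeration"`,
#'   `"fast_dissolution"`.
#' @param seed Integer seed; identical seeds reproduce identical fixtures.
#' @param meta An [acquisition_meta()].
#' @param elem An [element_params()].
#' @return A list: `scenario`, `fresh` and `aged`, each of the latter a
#'   [simulate_timescan()] result (`scan`, `truth`).
#' @export
generate_scenario_suite <- function(scenario, seed,
                                    meta = acquisition_meta(),
                                    elem = element_params()) {
  p <- scenario_params(scenario)
  set.seed(seed)
  make <- function(s) {
    cfg <- simulation_config(
      number_concentration = s$conc, size_median = s$median,
      size_gsd = s$gsd, second_mode = s$second,
      dissolved_concentration = s$dissolved
    )
    simulate_timescan(cfg, meta, elem)
  }
  list(scenario = scenario, fresh = make(p$fresh), aged = make(p$aged))
}

#' Match detected events to simulated ground truth
#'
#' A truth particle is matched to the first event whose dwell span,
#' extended by `tol` dwells on both sides, contains the particle's arrival
#' dwell. Used in closed-loop validation (recall, per-particle size error).
#'
#' @param events Events from [detect_events()].
#' @param truth Ground-truth tibble from the simulator.
#' @param tol Dwell tolerance (default 2).
#' @return `truth` with an added `event` column (row index into `events`,
#'   `NA` when undetected) and the matched `integrated_counts`.
#' @export
match_events_to_truth <- function(events, truth, tol = 2) {
  starts <- events$start_dwell - tol
  ends <- events$start_dwell + events$n_dwells - 1L + tol
  idx <- vapply(truth$arrival_dwell, function(a) {
    j <- which(starts <= a & ends >= a)
    if (length(j)) j[[1]] else NA_integer_
  }, integer(1))
  dplyr::mutate(
    truth,
    event = idx,
    integrated_counts = ifelse(is.na(idx), NA_real_,
                               events$integrated_counts[idx])
  )
}
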