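# Shared instrument fixtures: the nominal operating point used throughout
# (0.35 mL/min uptake, 7.5% transport efficiency, 1e6 cps/(ug/L) slope).

std_flow <- function() flow_rate(0.35e-3 / 60)

std_eta <- function(eta = 0.075) transport_efficiency(eta, std_flow())

std_cal <- function(slope = 1e6, intercept = 0) {
  ionic_calibration(slope, intercept)
}

# short acquisition for cheap unit tests (1e5 dwells = 10 s)
short_meta <- function(total_time = 10, ...) {
  acquisition_meta(total_time = total_time, ...)
}

# a simulation at the nominal operating point scaled to `total_time`,
# keeping the expected event count at `lambda`
std_sim <- function(lambda = 300, total_time = 10, dissolved = 0.5,
                    size_median = 59, size_gsd = 1.3, second_mode = NULL,
                    ...) {
  eta <- 0.075
  q <- 0.35e-3 / 60
  cfg <- simulation_config(
    number_concentration = lambda / (eta * q * total_time),
    size_median = size_median, size_gsd = size_gsd,
    second_mode = second_mode,
    dissolved_concentration = dissolved, ...)
  simulate_timescan(cfg, short_meta(total_time), element_params())
}
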