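test_that("ionic calibration recovers an exact line", {
  pts <- tibble::tibble(concentration_ug_L = c(0, 5, 10, 20, 30, 40, 50),
                        response_cps = 1000 * c(0, 5, 10, 20, 30, 40, 50) + 50)
  cal <- fit_ionic_calibration(pts)
  expect_equal(cal$slope_s, 1000)
  expect_equal(cal$intercept, 50)
  expect_equal(cal$r_squared, 1)
})

test_that("noisy calibration matches the closed-form least-squares oracle", {
  withr::local_seed(51)
  conc <- c(0, 5, 10, 20, 30, 40, 50)
  resp <- 1000 * conc + 50 + rnorm(7, 0, 0.01 * (1000 * 50))
  cal <- fit_ionic_calibration(
    tibble::tibble(concentration_ug_L = conc, response_cps = resp))
  slope_oracle <- sum((conc - mean(conc)) * (resp - mean(resp))) /
    sum((conc - mean(conc))^2)
  intercept_oracle <- mean(resp) - slope_oracle * mean(conc)
  expect_equal(cal$slope_s, slope_oracle, tolerance = 1e-10)
  expect_equal(cal$intercept, intercept_oracle, tolerance = 1e-10)
  expect_lt(abs(cal$slope_s - 1000) / 1000, 0.02)
})

test_that("degenerate calibration input errors", {
  expect_error(fit_ionic_calibration(
    tibble::tibble(concentration_ug_L = c(10, 10, 10),
                   response_cps = c(1, 2, 3))), "distinct")
  expect_error(fit_ionic_calibration(
    tibble::tibble(concentration_ug_L = c(0, Inf),
                   response_cps = c(0, 1))), "finite")
})

test_that("counts-per-dwell responses convert to the per-second basis", {
  pts <- tibble::tibble(concentration_ug_L = c(0, 10, 20),
                        response_counts_per_dwell = c(0, 1, 2))
  cal <- fit_ionic_calibration(pts, response_unit = "counts_per_dwell",
                               dwell_time = 1e-4)
  expect_equal(cal$slope_s, 1e3)  # 0.1 counts/dwell per ug/L -> 1e3 cps
  expect_error(fit_ionic_calibration(pts, response_unit = "counts_per_dwell"),
               "dwell_time")
})

test_that("gravimetric flow-rate arithmetic matches the 0.35 mL/min anchor", {
  fl <- measure_flow_rate(tibble::tibble(mass_g = rep(0.70, 3),
                                         duration_s = 120))
  expect_equal(fl$Q_mL_min, 0.35)
  expect_equal(fl$Q_sam, 0.35e-3 / 60, tolerance = 1e-12)

  fl <- measure_flow_rate(tibble::tibble(mass_g = c(0.6, 0.7, 0.8),
                                         duration_s = 120))
  expect_equal(fl$Q_mL_min, 0.35)

  expect_error(measure_flow_rate(tibble::tibble(mass_g = 0, duration_s = 120)),
               "> 0")
})

test_that("transport efficiency reproduces the hand-worked reference case", {
  # 50 nm Au, slope 5e5 cps/(ug/L), mean event 1000 counts, Q = 0.35 mL/min
  ev <- tibble::tibble(start_dwell = 1:60, n_dwells = 1L,
                       integrated_counts = 1000, peak_counts = 500L)
  eta <- transport_efficiency_particle_size(
    ev, d_ref = 50, rho_ref = 19.30,
    cal = std_cal(5e5), flow = std_flow())
  m_ref <- 19.30 * (pi / 6) * (50e-7)^3 * 1e6
  expect_equal(eta$eta_neb, m_ref * 5e5 / (1000 * 0.35e-3 / 60),
               tolerance = 1e-12)
  expect_equal(eta$eta_neb, 0.1083, tolerance = 1e-3)
  expect_equal(eta$K_intr, eta$eta_neb * 0.35e-3 / 60, tolerance = 1e-12)
})

test_that("transport efficiency is linear in slope and inverse in counts", {
  ev <- tibble::tibble(start_dwell = 1:100, n_dwells = 1L,
                       integrated_counts = 5000, peak_counts = 1L)
  base <- transport_efficiency_particle_size(ev, 50, 19.30, std_cal(2e5),
                                             std_flow())$eta_neb
  double_slope <- transport_efficiency_particle_size(
    ev, 50, 19.30, std_cal(4e5), std_flow())$eta_neb
  ev2 <- dplyr::mutate(ev, integrated_counts = integrated_counts * 2)
  half_counts <- transport_efficiency_particle_size(
    ev2, 50, 19.30, std_cal(2e5), std_flow())$eta_neb
  expect_equal(double_slope, 2 * base, tolerance = 1e-12)
  expect_equal(half_counts, base / 2, tolerance = 1e-12)
})

test_that("inconsistent reference runs are rejected or flagged", {
  ev <- tibble::tibble(start_dwell = 1:60, n_dwells = 1L,
                       integrated_counts = 1, peak_counts = 1L)
  expect_error(
    transport_efficiency_particle_size(ev, 50, 19.30, std_cal(5e5),
                                       std_flow()),
    "outside")
  ev_few <- tibble::tibble(start_dwell = 1:10, n_dwells = 1L,
                           integrated_counts = 1e4, peak_counts = 1L)
  expect_warning(
    transport_efficiency_particle_size(ev_few, 50, 19.30, std_cal(5e5),
                                       std_flow()),
    "recommended")
})

test_that("a simulated reference run closes the loop on the paper's 7.5%", {
  cfg <- simulation_config(size_gsd = 1, dissolved_concentration = 0.05,
                           number_concentration = 600 / (0.075 * 0.35e-3 / 60 * 10),
                           transport_efficiency = 0.075, seed = 52)
  sim <- simulate_reference_standard(50, 19.30, cfg, short_meta(10))
  ev <- detect_events(sim$scan, estimate_baseline(sim$scan))
  eta <- transport_efficiency_particle_size(ev, 50, 19.30, std_cal(1e6),
                                            std_flow())
  expect_lt(abs(eta$eta_neb - 0.075) / 0.075, 0.05)
})
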