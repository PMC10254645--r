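test_that("event mass follows the counts-to-mass relation", {
  cal <- std_cal(1e6)
  fl <- std_flow()
  eta <- std_eta(0.075)
  expect_equal(event_mass(2.285714285714e3, cal, fl, eta), 1e-9,
               tolerance = 1e-6)
  expect_equal(event_mass(0, cal, fl, eta), 0)
  expect_equal(event_mass(1000, cal, fl, eta),
               2 * event_mass(500, cal, fl, eta))
  expect_error(event_mass(-1, cal, fl, eta), ">= 0")
})

test_that("sphere sizing converts mass to diameter and back", {
  elem <- element_params()
  expect_equal(mass_to_diameter(5.15e-10, elem), 50, tolerance = 1e-3)
  expect_equal(mass_to_diameter(0, elem), 0)
  m <- 3.7e-10
  expect_equal(mass_to_diameter(8 * m, elem), 2 * mass_to_diameter(m, elem),
               tolerance = 1e-12)
  # inverse checked by recomputing mass from the diameter
  expect_equal(diameter_to_mass(mass_to_diameter(m, elem), elem), m,
               tolerance = 1e-12)
})

test_that("number concentration reproduces the worked arithmetic", {
  meta <- acquisition_meta(total_time = 120, dilution_factor = 1)
  nc <- number_concentration(300, std_flow(), std_eta(0.075), meta)
  expect_equal(nc$number_per_L, 5.714286e6, tolerance = 1e-6)
  expect_equal(number_concentration(0, std_flow(), std_eta(), meta)$number_per_L, 0)

  meta10 <- acquisition_meta(total_time = 120, dilution_factor = 10,
                             extract_volume = 8.5e-3, tissue_mass = 0.015)
  nc10 <- number_concentration(300, std_flow(), std_eta(0.075), meta10)
  # dilution scales per-L; per-gram adds extract_volume / tissue_mass
  expect_equal(nc10$number_per_L, 10 * nc$number_per_L)
  expect_equal(nc10$number_per_gram,
               nc10$number_per_L * 8.5e-3 / 0.015)
})

test_that("dissolved concentration inverts the baseline relation", {
  meta <- acquisition_meta()
  cal <- ionic_calibration(1e6, intercept = 500)
  st <- structure(list(I_b = 500 * 1e-4, sigma_b = 0, multiplier = 5),
                  class = "baseline_stats")
  expect_equal(dissolved_concentration(st, cal, meta), 0)  # baseline = blank
  st$I_b <- (500 + 2e6) * 1e-4  # 2 ug/L above blank
  expect_equal(dissolved_concentration(st, cal, meta), 2)
  bad_cal <- structure(list(slope_s = 0, intercept = 0),
                       class = "ionic_calibration")
  expect_error(dissolved_concentration(st, bad_cal, meta), "> 0")
  expect_warning(
    dissolved_concentration(
      structure(list(I_b = 0, sigma_b = 0, multiplier = 5),
                class = "baseline_stats"), cal, meta),
    "floor")
})

test_that("dissolved concentration closes the loop on a simulation", {
  withr::local_seed(61)
  sim <- std_sim(lambda = 200, total_time = 20, dissolved = 2)
  st <- estimate_baseline(sim$scan)
  rec <- dissolved_concentration(st, std_cal(1e6), scan_meta(sim$scan))
  expect_lt(abs(rec - 2) / 2, 0.02)
})

test_that("detection-efficiency product follows R / (K_intr C_M)", {
  expect_equal(detection_efficiency_product(1000, 1, 4.375e-7),
               2.285714e9, tolerance = 1e-6)
  expect_equal(detection_efficiency_product(2000, 1, 4.375e-7),
               2 * detection_efficiency_product(1000, 1, 4.375e-7))
  expect_error(detection_efficiency_product(1000, 0, 4.375e-7), "> 0")
})

test_that("size detection limit matches hand arithmetic and scaling", {
  elem <- element_params()
  k <- 2.285714285714e9
  expect_equal(size_lod(1, elem, k), 68.293, tolerance = 1e-4)
  expect_equal(size_lod(8, elem, k), 2 * size_lod(1, elem, k),
               tolerance = 1e-12)
  expect_error(size_lod(0, elem, k), "> 0")
})

test_that("the LOD computed via the printed formula equals the mass route", {
  withr::local_seed(62)
  for (i in 1:50) {
    sigma <- runif(1, 0.1, 50)
    k <- 10^runif(1, 7, 12)
    elem <- element_params(density_rho = runif(1, 2, 20),
                           mass_fraction_X = runif(1, 0.3, 1))
    expect_equal(size_lod(sigma, elem, k),
                 mass_to_diameter(3 * sigma / k, elem),
                 tolerance = 1e-12)
  }
})

test_that("signal-to-noise selects the best gas flow and flags zero noise", {
  withr::local_seed(63)
  flows <- c("4", "5", "6", "7")
  mk_trace <- function(sdev) {
    timescan(pmax(0, round(rnorm(1e4, 100, sdev))), short_meta(1))
  }
  traces <- list(`4` = mk_trace(10), `5` = mk_trace(10), `6` = mk_trace(10),
                 `7` = mk_trace(10))
  resp <- c(`4` = 800, `5` = 950, `6` = 1200, `7` = 900)
  sn <- signal_to_noise(resp, traces)
  expect_equal(attr(sn, "best_flow"), "6")
  # moment oracle: delta is the per-second SD of the matrix trace
  expect_equal(sn$delta_cps[1], sd(traces[["4"]]$counts) / 1e-4)

  traces$`5` <- timescan(rep(100L, 1e4), short_meta(1))  # zero noise
  sn <- signal_to_noise(resp, traces)
  expect_true(sn$undefined[sn$gas_flow == "5"])
  expect_equal(attr(sn, "best_flow"), "6")
})

test_that("full sample reduction is coherent end to end", {
  withr::local_seed(64)
  sim <- std_sim(lambda = 250, total_time = 20)
  res <- analyze_timescan(sim$scan, std_cal(1e6), std_flow(), std_eta(0.075))
  expect_s3_class(res, "sample_result")
  expect_gt(res$n_events, 200)
  # number x mean mass consistency: particulate equals n * mean event mass
  expect_equal(res$particulate_ug_L,
               res$number_per_L * mean(res$events$mass_ug),
               tolerance = 1e-9)
  expect_lt(abs(res$dissolved_ug_L - 0.5) / 0.5, 0.02)
  expect_lt(res$lod_nm, 25)
  g <- glance(res)
  expect_equal(g$n_events, res$n_events)
  expect_equal(nrow(g), 1)
})
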