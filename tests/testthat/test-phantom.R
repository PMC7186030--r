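test_that("phantom geometry satisfies its construction invariants", {
  ph <- fx_phantom()
  m <- ph$masks
  # every labelled pixel inside the unit disk
  expect_true(all(which(ph$labels > 0L) %in% which(m$disk)))
  # regions pairwise disjoint
  expect_equal(sum(m$right_lung & m$left_lung), 0)
  expect_equal(sum(m$right_lung & m$heart), 0)
  expect_equal(sum(m$left_lung & m$heart), 0)
  # lateral symmetry of the lungs up to discretization
  a <- sum(m$right_lung); b <- sum(m$left_lung)
  expect_lt(abs(a - b) / min(a, b), 0.05)
  # conductivities strictly positive, air-filled lung below background
  expect_true(all(ph$conductivity > 0))
  expect_lt(ph$conductivity[["lung"]], ph$conductivity[["background"]])
  expect_true(all(ph$sigma0[m$disk] > 0))
})

test_that("region area fractions are resolution-consistent", {
  frac <- function(n) {
    ph <- build_phantom(n)
    vapply(ph$masks[c("right_lung", "left_lung", "heart")], sum, 0L) /
      sum(ph$masks$disk)
  }
  expect_lt(max(abs(frac(32) - frac(128))), 0.03)
})

test_that("too-coarse grids and bad conductivities are rejected", {
  expect_error(build_phantom(31), class = "eitperf_error_parameter")
  expect_error(build_phantom(64, conductivity = c(background = 1, lung = 2, heart = 1.5)),
               class = "eitperf_error_parameter")
})

test_that("gamma-variate bolus satisfies its analytic contract", {
  t0 <- 2; tp <- 4; alpha <- 3; amp <- 0.7
  # causality and analytic maximum
  expect_equal(bolus_concentration(seq(-2, t0, by = 0.1), t0, tp, alpha, amp),
               rep(0, length(seq(-2, t0, by = 0.1))))
  expect_equal(bolus_concentration(t0 + tp, t0, tp, alpha, amp), amp)
  tt <- seq(0, 60, by = 0.01)
  expect_lte(max(bolus_concentration(tt, t0, tp, alpha, amp)), amp + 1e-12)
  # amplitude linearity of the integral
  i1 <- sum(bolus_concentration(tt, t0, tp, alpha, amp)) * 0.01
  i2 <- sum(bolus_concentration(tt, t0, tp, alpha, 2 * amp)) * 0.01
  expect_equal(i2 / i1, 2, tolerance = 1e-12)
  expect_error(bolus_concentration(1, t0, tp = 0, alpha), class = "eitperf_error_parameter")
  expect_error(bolus_concentration(1, t0, tp, alpha = -1), class = "eitperf_error_parameter")
})

test_that("scenario configuration enforces the protocol", {
  expect_error(scenario_config("ventilation_only", occluded_fraction = 0.3),
               class = "eitperf_error_config")
  expect_error(scenario_config("distal", bolus_volume_ml = 20),
               class = "eitperf_error_config")
  expect_error(scenario_config("proximal_deflated", bolus_volume_ml = 15),
               class = "eitperf_error_config")
  expect_error(scenario_config("distal", flow_split = c(right = 0.7, left = 0.5)),
               class = "eitperf_error_config")
  expect_equal(scenario_config("distal")$bolus_volume_ml, 15)
  expect_equal(scenario_config("proximal_inflated")$bolus_volume_ml, 20)
  # bolus scenarios default to a breath hold at end-expiration
  expect_true(scenario_config("distal")$breath_hold)
  expect_false(scenario_config("ventilation_only")$breath_hold)
})

test_that("ventilation modulates lung conductivity with 15 complete periods in 77 s", {
  ph <- fx_phantom()
  ser <- cached("vent1000_fields", {
    simulate_scenario(ph, scenario_config("ventilation_only"), n_frames = 1000)
  })
  px <- which(ph$masks$left_lung)[10]
  r <- (px - 1) %% 64 + 1; cl <- (px - 1) %/% 64 + 1
  z <- ser$fields[r, cl, ]
  # count complete minimum-to-minimum conductivity cycles (inspiration
  # lowers lung conductivity, so minima mark end-inspiration)
  minima <- which(diff(sign(diff(z))) > 0) + 1
  expect_equal(length(minima), 15)
  # background pixel is unmodulated
  bg <- which(ph$masks$disk & ph$labels == 1L)[1]
  rb <- (bg - 1) %% 64 + 1; cb <- (bg - 1) %/% 64 + 1
  expect_equal(diff(range(ser$fields[rb, cb, ])), 0)
})

test_that("occluded sub-region stays constant under breath hold + occlusion", {
  fx <- fx_acquisition("proximal_inflated", n_frames = 120)
  terr <- fx$series$truth$masks$left_territory
  f <- fx$series$fields
  for (px in which(terr)[c(1, 10, 50)]) {
    r <- (px - 1) %% 64 + 1; cl <- (px - 1) %/% 64 + 1
    expect_equal(diff(range(f[r, cl, ])), 0)
  }
  # ground-truth AUC of the occluded territory is exactly zero
  reg <- fx$series$truth$regions
  expect_identical(reg$auc[reg$role == "ipsilateral_territory"], 0)
})

test_that("distal injection routes no indicator to the contralateral lung", {
  fx <- fx_acquisition("distal", n_frames = 200)
  cur <- fx$series$truth$curves
  contra <- cur$concentration[cur$region == "right_lung"]
  expect_identical(max(contra), 0)
  ipsi <- cur$concentration[cur$region == "left_territory"]
  expect_gt(max(ipsi), 0)
})

test_that("indicator mass (flow-weighted AUC) is invariant to the flow split", {
  ph <- fx_phantom()
  mass <- vapply(c(0.5, 1 / 3, 0.2), function(fr) {
    cfg <- scenario_config("proximal_deflated",
                           flow_split = c(right = fr, left = 1 - fr))
    reg <- eitperf:::scenario_regions(ph, cfg)$table
    lung <- reg$role != "heart"
    sum(reg$flow_fraction[lung] * reg$auc[lung])
  }, 0)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 0.01)
})

test_that("conductivity stays strictly positive and the generator is deterministic", {
  fx <- fx_acquisition("distal", n_frames = 200)
  vals <- fx$series$fields[!is.na(fx$series$fields)]
  expect_gt(min(vals), 0)
  ser2 <- simulate_scenario(fx_phantom(), fx$config, n_frames = 200)
  expect_identical(fx$series$fields, ser2$fields)
  expect_identical(fx$series$truth$curves, ser2$truth$curves)
})

test_that("territory mask is the dorsal-most fraction of the lung", {
  ph <- fx_phantom()
  terr <- territory_mask(ph, "left", 0.4)
  lung <- ph$masks$left_lung
  expect_true(all(which(terr) %in% which(lung)))
  expect_equal(sum(terr), round(0.4 * sum(lung)))
  # every territory pixel is at least as dorsal as every non-territory pixel
  g <- eitperf:::grid_coords(64)
  expect_lte(max(g$Y[terr]), min(g$Y[lung & !terr]) + g$h)
})
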