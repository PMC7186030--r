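# Synthetic dilution curve from analytic gamma-variate samples.
gamma_curve <- function(t0 = 2, tp = 4, alpha = 3, amp = 1, t_end = 40,
                        baseline_sd = 0) {
  tm <- seq(0, t_end, by = 0.077)
  cv <- tibble::tibble(time = tm, value = bolus_concentration(tm, t0, tp, alpha, amp))
  attr(cv, "baseline_sd") <- baseline_sd
  attr(cv, "location") <- "analytic"
  class(cv) <- c("dilution_curve", class(cv))
  cv
}

test_that("metrics of the analytic gamma-variate match closed-form oracles", {
  cv <- gamma_curve()
  met <- curve_metrics(cv)
  expect_true(met$defined)
  # peak at t0 + tp within one frame
  expect_lte(abs(met$time_to_peak - gamma_peak_time(2, 4)), 0.077)
  # appearance at the 5%-of-peak rising crossing (within two frames,
  # allowing for the 2-frame persistence rule)
  app_true <- gamma_appearance_analytic(2, 4, 3)
  expect_gte(met$appearance_time, app_true - 0.077)
  expect_lte(met$appearance_time, app_true + 2 * 0.077)
  expect_equal(met$appearance_to_peak, met$time_to_peak - met$appearance_time)
  # trapezoid AUC within 1% of dense quadrature over the same support rule
  expect_lt(abs(met$auc - gamma_auc_dense(2, 4, 3, 1)) / gamma_auc_dense(2, 4, 3, 1),
            0.01)
  # MTT within 2% of the analytic first moment t0 + tp (alpha+1)/alpha
  mtt_true <- gamma_mtt_analytic(2, 4, 3)
  expect_lt(abs(met$mean_transit_time - mtt_true) / mtt_true, 0.02)
})

test_that("metric shape-invariance: doubling amplitude doubles AUC only", {
  m1 <- curve_metrics(gamma_curve(amp = 1))
  m2 <- curve_metrics(gamma_curve(amp = 2))
  expect_equal(m2$auc / m1$auc, 2, tolerance = 1e-10)
  expect_lte(abs(m2$appearance_time - m1$appearance_time), 0.077)
  expect_lte(abs(m2$time_to_peak - m1$time_to_peak), 0.077)
})

test_that("truncated washout is recovered by gamma-variate extrapolation", {
  full <- curve_metrics(gamma_curve(t_end = 40))
  trunc <- curve_metrics(gamma_curve(t_end = 9))
  expect_lt(abs(trunc$auc - full$auc) / full$auc, 0.05)
  expect_lt(abs(trunc$mean_transit_time - full$mean_transit_time) /
              full$mean_transit_time, 0.05)
})

test_that("metric ordering invariants hold across random gamma curves", {
  set.seed(101)
  for (i in 1:25) {
    t0 <- runif(1, 0.5, 6); tp <- runif(1, 1, 8)
    alpha <- runif(1, 1, 6); amp <- runif(1, 0.2, 3)
    met <- curve_metrics(gamma_curve(t0, tp, alpha, amp, t_end = 60))
    expect_true(met$defined)
    expect_lte(met$appearance_time, met$time_to_peak)
    expect_gte(met$auc, 0)
    expect_gte(met$mean_transit_time, met$appearance_time)
    expect_equal(met$appearance_to_peak, met$time_to_peak - met$appearance_time)
  }
})

test_that("no-signal curves return undefined metrics, not zeros", {
  cv <- gamma_curve(amp = 0.01, baseline_sd = 0.01) # peak below 3 x SD
  met <- curve_metrics(cv)
  expect_false(met$defined)
  expect_true(is.na(met$auc))
  expect_true(is.na(met$mean_transit_time))
})

test_that("curve extraction: baselines, static series, determinism, errors", {
  fx <- fx_acquisition("distal", n_frames = 300)
  ref <- seq_len(injection_frame_of(fx$config) - 1L)
  imgs <- reconstruct_series(fx$acquisition, ref, fx_op())
  # static (pre-injection) portion: curve is exactly zero after baseline
  static <- imgs
  static$pixels <- imgs$pixels[, , rep(1L, 40)]
  static$times <- imgs$times[1:40]
  cv0 <- extract_curve(static, c(22, 23), 10)
  expect_equal(max(abs(cv0$value)), 0)
  # determinism: same extraction twice is identical
  cv1 <- extract_curve(imgs, c(22, 23), min(66, length(ref) + 1))
  cv2 <- extract_curve(imgs, c(22, 23), min(66, length(ref) + 1))
  expect_identical(cv1$value, cv2$value)
  # contracts
  expect_error(extract_curve(imgs, c(1, 1), 66), class = "eitperf_error_parameter")
  expect_error(extract_curve(imgs, c(16, 16), 5), class = "eitperf_error_parameter")
  expect_error(extract_curve(imgs, matrix(FALSE, 32, 32), 66),
               class = "eitperf_error_parameter")
})

test_that("ipsilateral dorsal curve carries signal; contralateral does not", {
  fx <- fx_acquisition("distal", n_frames = 300)
  ref <- seq_len(injection_frame_of(fx$config) - 1L)
  imgs <- reconstruct_series(fx$acquisition, ref,
                             fx_op("regularized_sensitivity"))
  px <- dorsal_pixels(recon_masks(fx$config))
  # noiseless: ipsilateral strong signal, contralateral nearly nothing
  ci <- extract_curve(imgs, px$left, length(ref) + 1L)
  cc <- extract_curve(imgs, px$right, length(ref) + 1L)
  expect_gt(max(ci$value), 10 * max(cc$value))
})

test_that("relative flow follows 1/AUC with occluded regions set to zero", {
  mk <- function(auc, defined = TRUE) {
    out <- tibble::tibble(
      location = "roi", defined = defined, peak_amplitude = 1,
      appearance_time = 1, time_to_peak = 2, appearance_to_peak = 1,
      auc = auc, mean_transit_time = 3
    )
    if (!defined) out[, -(1:2)] <- NA_real_
    class(out) <- c("curve_metrics", class(out))
    out
  }
  # equal AUCs -> exactly half/half
  fl <- estimate_relative_flow(list(right = mk(2), left = mk(2)))
  expect_equal(fl$relative_flow, c(0.5, 0.5))
  # 2:1 AUC ratio -> 1:2 flow ratio
  fl2 <- estimate_relative_flow(list(a = mk(2), b = mk(1)))
  expect_equal(fl2$relative_flow, c(1, 2) / 3)
  # undefined region -> flow 0, remainder renormalized
  fl3 <- estimate_relative_flow(list(a = mk(2), b = mk(NA, defined = FALSE),
                                     c = mk(2)))
  expect_equal(fl3$relative_flow, c(0.5, 0, 0.5))
  expect_error(estimate_relative_flow(list(a = mk(NA, defined = FALSE))),
               class = "eitperf_error_no_signal")
})

test_that("simulated 2:1 flow split is recovered from reconstructed 1/AUC", {
  fx <- fx_acquisition("proximal_deflated", n_frames = 400,
                       flow_split = c(right = 1 / 3, left = 2 / 3))
  ref <- seq_len(injection_frame_of(fx$config) - 1L)
  imgs <- reconstruct_series(fx$acquisition, ref,
                             fx_op("regularized_sensitivity"))
  met <- lung_roi_metrics(imgs, recon_masks(fx$config), length(ref) + 1L)
  fl <- estimate_relative_flow(met)
  truth <- c(right = 1 / 3, left = 2 / 3)
  expect_lt(max(abs(fl$relative_flow - truth) / truth), 0.1)
})

test_that("defect detection contracts: degenerate input, bad kinds, masks", {
  zero <- eitperf:::new_functional_image(matrix(0, 32, 32), disk_mask_32(),
                                         "perfusion", list())
  m <- recon_masks()
  lungs <- list(right = m$right_lung, left = m$left_lung)
  expect_error(detect_perfusion_defect(zero, lungs),
               class = "eitperf_error_degenerate_input")
  vent <- eitperf:::new_functional_image(matrix(1, 32, 32), disk_mask_32(),
                                         "ventilation", list())
  expect_error(detect_perfusion_defect(vent, lungs), class = "eitperf_error_parameter")
  ok <- eitperf:::new_functional_image(matrix(1, 32, 32), disk_mask_32(),
                                       "perfusion", list())
  expect_error(detect_perfusion_defect(ok, list(right = matrix(FALSE, 32, 32))),
               class = "eitperf_error_parameter")
  # uniform perfusion: no defects anywhere
  dd <- detect_perfusion_defect(ok, lungs)
  expect_equal(sum(dd$defect_map), 0)
  expect_equal(dd$fractions$defect_fraction, c(0, 0))
})
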