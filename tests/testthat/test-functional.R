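# Shared ventilation fixtures (4 breaths, 20 s).
fx_vent_images <- function(amplitude = 0.2) {
  cached(paste0("vent_imgs_", amplitude), {
    fx <- fx_acquisition("ventilation_only", n_frames = 260,
                         ventilation_conductivity_amplitude = amplitude)
    reconstruct_series(fx$acquisition, 1L, fx_op())
  })
}

test_that("breath segmentation finds the analytic extrema of a sinusoidal drive", {
  imgs <- fx_vent_images()
  seg <- segment_breaths(imgs, 12)
  expect_equal(seg$n_breaths, 4)
  # breath period 5 s: end-inspiration at (k + 1/2) * 5 s, end-expiration at k * 5 s
  dt <- 0.077
  exp_insp <- round(((0:3) + 0.5) * 5 / dt) + 1
  exp_exp <- round((0:4) * 5 / dt) + 1
  expect_equal(length(seg$end_inspiration_indices), 4)
  expect_true(all(abs(seg$end_inspiration_indices - exp_insp) <= 1))
  expect_true(all(abs(sort(seg$end_expiration_indices) - exp_exp) <= 1))
  # alternation: every end-inspiration lies between two end-expirations
  for (i in seg$end_inspiration_indices) {
    expect_true(any(seg$end_expiration_indices < i) &&
                  any(seg$end_expiration_indices > i))
  }
})

test_that("constant series yields an insufficient-signal error", {
  fx <- fx_acquisition("proximal_inflated", n_frames = 120)
  imgs <- reconstruct_series(fx$acquisition, 1:60, fx_op())
  static <- imgs
  static$pixels <- array(0, dim(imgs$pixels))
  expect_error(segment_breaths(static, 12), class = "eitperf_error_insufficient_signal")
})

test_that("ventilation image highlights the lungs and scales with tidal amplitude", {
  m <- recon_masks()
  lung <- m$right_lung | m$left_lung
  imgs <- fx_vent_images()
  vi <- ventilation_image(imgs, segment_breaths(imgs, 12))
  expect_identical(vi$kind, "ventilation")
  v <- vi$pixels
  thr <- quantile(v[m$disk], 0.9)
  top <- v > thr & m$disk
  expect_gte(sum(top & lung) / sum(top), 0.9)

  # doubling the tidal conductivity amplitude ~doubles the in-lung mean
  v2 <- ventilation_image(fx_vent_images(0.1),
                          segment_breaths(fx_vent_images(0.1), 12))$pixels
  ratio <- mean(v[lung]) / mean(v2[lung])
  expect_gte(ratio, 1.6); expect_lte(ratio, 2.4)
})

test_that("breath-hold series yields a near-zero ventilation image", {
  fx <- fx_acquisition("proximal_inflated", n_frames = 120)
  imgs <- reconstruct_series(fx$acquisition, 1:60, fx_op())
  # nominal segmentation indices inside the static pre-injection window
  seg <- list(end_inspiration_indices = c(15L, 45L),
              end_expiration_indices = c(5L, 30L, 55L))
  vi <- ventilation_image(imgs, seg)
  expect_lt(max(abs(vi$pixels)), 1e-12)
})

test_that("perfusion image is lateralized as the injection scenario dictates", {
  m_d <- recon_masks(scenario_config("distal", catheter_side = "left"))
  fx <- fx_acquisition("distal", n_frames = 300)
  ref <- seq_len(injection_frame_of(fx$config) - 1L)
  imgs <- reconstruct_series(fx$acquisition, ref, fx_op())
  arr <- detect_bolus_arrival(imgs, m_d$right_lung | m_d$left_lung, ref)
  pf <- perfusion_image(imgs, ref, arr)
  expect_identical(pf$kind, "perfusion")
  p <- pf$pixels
  # top-decile positive pixels concentrate in the left dorsal territory
  top <- p > quantile(p[pf$mask], 0.9) & pf$mask
  expect_gt(sum(top & m_d$territory) / sum(top), 0.5)
  # contralateral mean under 20% of ipsilateral mean
  expect_lt(mean(p[m_d$right_lung]), 0.2 * mean(p[m_d$left_lung]))

  # deflated balloon: both lungs carry top-decile pixels
  fx2 <- fx_acquisition("proximal_deflated", n_frames = 300)
  imgs2 <- reconstruct_series(fx2$acquisition, ref, fx_op())
  arr2 <- detect_bolus_arrival(imgs2, m_d$right_lung | m_d$left_lung, ref)
  pf2 <- perfusion_image(imgs2, ref, arr2)
  top2 <- pf2$pixels > quantile(pf2$pixels[pf2$mask], 0.9) & pf2$mask
  expect_gt(sum(top2 & m_d$right_lung), 0)
  expect_gt(sum(top2 & m_d$left_lung), 0)

  # an arrival window placed before the injection sees no bolus
  pf0 <- perfusion_image(imgs, 1:20, 40L)
  expect_lt(max(abs(pf0$pixels)), 1e-12)
  expect_error(perfusion_image(imgs, ref, max(ref)), class = "eitperf_error_parameter")
})

test_that("bolus arrival detection matches the truth and honours its contracts", {
  fx <- fx_acquisition("distal", n_frames = 300)
  ref <- seq_len(injection_frame_of(fx$config) - 1L)
  imgs <- reconstruct_series(fx$acquisition, ref, fx_op())
  m <- recon_masks(fx$config)
  arr <- detect_bolus_arrival(imgs, m$left_lung, ref)
  truth <- fx$series$truth$curves
  terr <- truth[truth$region == "left_territory", ]
  expect_lte(abs(arr - which.max(terr$concentration)), 2)

  # flat series: no arrival
  flat <- imgs; flat$pixels <- array(0, dim(imgs$pixels))
  expect_error(detect_bolus_arrival(flat, m$left_lung, ref),
               class = "eitperf_error_no_arrival")

  # gentle monotone drift within the noise floor: depth criterion rejects it
  set.seed(42)
  drift <- imgs
  nT <- dim(imgs$pixels)[3]
  z <- rnorm(nT, sd = 1) - seq(0, 0.5, length.out = nT)
  drift$pixels <- array(rep(z, each = 1024), c(32, 32, nT))
  expect_error(detect_bolus_arrival(drift, m$left_lung, 1:60),
               class = "eitperf_error_no_arrival")

  # tie-break: two equal minima return the earlier index
  two <- imgs; two$pixels <- array(0, c(32, 32, 20))
  two$pixels[, , 8] <- -1; two$pixels[, , 14] <- -1
  expect_equal(detect_bolus_arrival(two, m$left_lung, 1:5), 8L)

  expect_error(detect_bolus_arrival(imgs, matrix(FALSE, 32, 32), ref),
               class = "eitperf_error_parameter")
})

test_that("ventilation image is stable to a one-breath shift of the averaging window", {
  imgs <- fx_vent_images()
  seg <- segment_breaths(imgs, 12)
  v_all <- ventilation_image(imgs, seg)$pixels
  seg2 <- list(end_inspiration_indices = seg$end_inspiration_indices[-1],
               end_expiration_indices = seg$end_expiration_indices)
  v_shift <- ventilation_image(imgs, seg2)$pixels
  m <- recon_masks(); lung <- m$right_lung | m$left_lung
  expect_lt(max(abs(v_all[lung] - v_shift[lung])) / max(abs(v_all[lung])), 0.05)
})
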