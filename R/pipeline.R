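# End-to-end conveniences tying the pipeline together:
# simulate -> acquire -> reconstruct -> functional images -> dilution.

#' Region masks on the 32x32 reconstruction grid
#'
#' Rebuilds the phantom geometry analytically at the reconstruction
#' resolution and adds the branch-territory split used by a scenario.
#'
#' @param config Optional [scenario_config()]; when given and the scenario
#'   involves the catheterised branch, `territory` and `ipsi_rest` masks
#'   are included.
#' @return Named list of logical 32x32 masks (`disk`, `right_lung`,
#'   `left_lung`, `heart`, and optionally `territory`, `ipsi_rest`,
#'   `contra`).
#' @export
recon_masks <- function(config = NULL) {
  ph <- build_phantom(IMG_N)
  masks <- ph$masks
  if (!is.null(config) && config$scenario != "ventilation_only") {
    side <- config$catheter_side
    terr <- territory_mask(ph, side, config$occluded_fraction)
    masks$territory <- terr
    masks$ipsi_rest <- ph$masks[[paste0(side, "_lung")]] & !terr
    masks$contra <- ph$masks[[paste0(if (side == "left") "right" else "left", "_lung")]]
  }
  masks
}

#' Dorsal sampling pixels of both lungs
#'
#' The pixel locations at which local time-impedance curves are sampled:
#' the centroid of the dorsal-most `frac` of each lung mask, placed at a
#' common vertical height (curves are compared between a lung region
#' supplied by the catheterised vessel and the contralateral lung at the
#' same height).
#'
#' @param masks A [recon_masks()] result.
#' @param frac Dorsal fraction of each lung used (default 0.3).
#' @return List with `right` and `left`, each `c(row, col)`.
#' @export
dorsal_pixels <- function(masks, frac = 0.3) {
  g <- grid_coords(IMG_N)
  one <- function(m) {
    idx <- which(m)
    ord <- order(g$Y[idx]) # most dorsal first
    sel <- idx[ord][seq_len(max(1L, round(frac * length(idx))))]
    rr <- (sel - 1L) %% IMG_N + 1L
    cc <- (sel - 1L) %/% IMG_N + 1L
    c(row = round(mean(rr)), col = round(mean(cc)))
  }
  r <- one(masks$right_lung); l <- one(masks$left_lung)
  common_row <- round((r[["row"]] + l[["row"]]) / 2)
  list(right = c(row = common_row, col = r[["col"]]),
       left = c(row = common_row, col = l[["col"]]))
}

#' Run one scenario end to end
#'
#' Simulates the conductivity series, acquires boundary voltages,
#' reconstructs the image sequence against a pre-injection (or first-frame)
#' reference, and — for bolus scenarios — detects the bolus arrival in the
#' whole-lung ROI and derives the perfusion image, per-lung dorsal dilution
#' curves and their metrics.
#'
#' @param config A [scenario_config()].
#' @param grid_n Phantom simulation grid (default 64).
#' @param n_frames Frames to simulate (default 400 = 30.8 s).
#' @param op A [build_operator()] (default: back-projection), reused across
#'   calls if supplied.
#' @param system Optional cached forward solver.
#' @param noise_sd,seed Overrides passed to [simulate_acquisition()].
#' @param smooth_frames Moving-average width for the dorsal pixel curves
#'   (default 9 frames = 0.69 s, narrow against the ~100-frame bolus
#'   transit; see [extract_curve()]).
#' @return List with `series`, `acquisition`, `images`, `masks`,
#'   `reference` indices and, for bolus scenarios, `arrival_index`,
#'   `perfusion`, `curves` (named list of dilution curves) and `metrics`
#'   (curve-metrics tibble with a `region` column).
#' @export
run_scenario <- function(config, grid_n = 64, n_frames = 400,
                         op = build_operator(), system = NULL,
                         noise_sd = NULL, seed = NULL, smooth_frames = 9L) {
  stopifnot(inherits(config, "scenario_config"))
  series <- simulate_scenario(build_phantom(grid_n), config, n_frames = n_frames)
  acq <- simulate_acquisition(series, op$layout, op$pattern,
                              noise_sd = noise_sd, seed = seed, system = system)
  inj_frame <- floor(config$injection_time_s / EIT_DT) + 1L
  is_bolus <- config$scenario != "ventilation_only"
  reference <- if (is_bolus) seq_len(inj_frame - 1L) else 1L
  images <- reconstruct_series(acq, reference, op)
  masks <- recon_masks(config)
  out <- list(series = series, acquisition = acq, images = images,
              masks = masks, reference = reference, config = config,
              injection_frame = inj_frame)
  if (is_bolus) {
    lung_roi <- masks$right_lung | masks$left_lung
    out$arrival_index <- detect_bolus_arrival(images, lung_roi,
                                              baseline_frames = reference)
    out$perfusion <- perfusion_image(images, reference, out$arrival_index)
    px <- dorsal_pixels(masks)
    out$curves <- lapply(px, function(p) {
      extract_curve(images, p, inj_frame, smooth_frames = smooth_frames)
    })
    out$metrics <- dplyr::bind_rows(lapply(names(out$curves), function(nm) {
      dplyr::mutate(curve_metrics(out$curves[[nm]]), region = nm)
    }))
  }
  out
}

#' Per-lung dilution metrics from whole-lung ROI curves
#'
#' Extracts ROI-mean dilution curves over each lung mask and computes their
#' metrics; input to [estimate_relative_flow()].
#'
#' @param images An `impedance_series`.
#' @param masks A [recon_masks()] result.
#' @param injection_frame Injection frame index.
#' @return `curve_metrics` tibble with a `region` column
#'   (`"right"`/`"left"`).
#' @export
lung_roi_metrics <- function(images, masks, injection_frame) {
  dplyr::bind_rows(lapply(c("right", "left"), function(s) {
    cv <- extract_curve(images, masks[[paste0(s, "_lung")]], injection_frame)
    dplyr::mutate(curve_metrics(cv), region = s)
  }))
}
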