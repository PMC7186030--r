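# Local time-impedance dilution curves and indicator-dilution metrics:
# area under the curve (Stewart-Hamilton), appearance time, appearance-to-
# peak time, mean transit time; relative regional flow estimation and
# perfusion-defect detection.

#' Extract a local time-impedance dilution curve
#'
#' Baseline-subtracted, sign-flipped pixel (or ROI-mean) time course:
#' `value = baseline_mean - pixel value`, so the impedance fall on bolus
#' arrival is positive. The baseline is the mean over all frames strictly
#' before `injection_frame` (at least 5 frames).
#'
#' @param images An `impedance_series` from [reconstruct_series()].
#' @param location Either `c(row, col)` pixel coordinates (row 1 =
#'   ventral, col 1 = animal's right) or a logical 32x32 ROI mask.
#' @param injection_frame Frame index of the injection (>= 6 so that at
#'   least 5 baseline frames exist).
#' @param smooth_frames Width (frames) of a centred moving-average filter
#'   applied to the raw pixel signal before baseline subtraction — the
#'   usual low-pass preprocessing of indicator-dilution curves (1 =
#'   none, the default; the bolus transit spans ~100 frames, so widths of
#'   5-9 frames do not bias the curve shape). The reported `baseline_sd`
#'   is that of the unsmoothed pre-injection signal.
#' @return Object of class `dilution_curve`: a tibble with columns `time`
#'   (s) and `value` (impedance fall, a.u.), with attributes
#'   `baseline_mean`, `baseline_sd`, `location` (label string) and
#'   `injection_frame`.
#' @export
extract_curve <- function(images, location, injection_frame, smooth_frames = 1L) {
  stopifnot(inherits(images, "impedance_series"))
  injection_frame <- as.integer(injection_frame)
  smooth_frames <- as.integer(smooth_frames)
  if (smooth_frames < 1L || smooth_frames %% 2L != 1L) {
    eit_abort("`smooth_frames` must be an odd positive integer.", "parameter")
  }
  if (injection_frame < 6L) {
    eit_abort("`injection_frame` must be >= 6 (need >= 5 baseline frames).", "parameter")
  }
  if (is.logical(location)) {
    if (!any(location & images$mask)) {
      eit_abort("ROI mask is empty inside the circular support.", "parameter")
    }
    m <- location & images$mask
    z <- apply(images$pixels, 3, function(p) mean(p[m]))
    label <- sprintf("roi[%d px]", sum(m))
  } else {
    location <- as.integer(location)
    if (length(location) != 2L || any(location < 1L) || any(location > IMG_N) ||
        !images$mask[location[1], location[2]]) {
      eit_abort("`location` must be a pixel inside the circular support.", "parameter")
    }
    z <- images$pixels[location[1], location[2], ]
    label <- sprintf("pixel(%d,%d)", location[1], location[2])
  }
  base <- z[seq_len(injection_frame - 1L)]
  zs <- if (smooth_frames > 1L) {
    k <- rep(1 / smooth_frames, smooth_frames)
    as.numeric(stats::filter(z, k, sides = 2))
  } else z
  # moving-average edges: fall back to the raw signal
  zs[is.na(zs)] <- z[is.na(zs)]
  curve <- tibble(time = images$times, value = mean(base) - zs)
  structure(curve,
            class = c("dilution_curve", class(curve)),
            baseline_mean = mean(base), baseline_sd = sd(base),
            location = label, injection_frame = injection_frame,
            smooth_frames = smooth_frames)
}

# Least-squares gamma-variate fit used to extrapolate a truncated washout.
# Returns NULL if the fit fails.
fit_gamma_variate <- function(time, value) {
  ipk <- which.max(value)
  start <- list(
    t0 = max(min(time), time[ipk] - 4),
    tp = max(2 * diff(time[1:2]), time[ipk] - max(min(time), time[ipk] - 4)),
    alpha = 3,
    amp = max(value)
  )
  fit <- try(minpack.lm::nlsLM(
    value ~ ifelse(time > t0, amp * ((time - t0) / tp)^alpha *
                     exp(alpha * (1 - (time - t0) / tp)), 0),
    data = list(time = time, value = value), start = start,
    lower = c(t0 = min(time) - 10, tp = 1e-3, alpha = 0.2, amp = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  as.list(coef(fit))
}

#' Indicator-dilution metrics of one curve
#'
#' Computes the Stewart-Hamilton curve parameters: `appearance_time` (first
#' time the curve exceeds `appearance_fraction` x peak and stays above for
#' at least 2 frames), `time_to_peak` (argmax), `appearance_to_peak`,
#' `auc` (trapezoidal integral from appearance to the first return below
#' the appearance level; if the record ends first, the washout is
#' extrapolated by a gamma-variate fit) and `mean_transit_time` (first
#' temporal moment over the same support).
#'
#' A curve whose peak does not exceed 3x the baseline SD (or is not
#' positive) carries no signal: all metrics are returned as `NA` with
#' `defined = FALSE`, not as numeric zeros.
#'
#' @param curve A [extract_curve()] result (tibble with `time`, `value`;
#'   baseline SD read from the attribute, 0 if absent).
#' @param appearance_fraction Appearance threshold as a fraction of the
#'   peak (default 0.05).
#' @return Object of class `curve_metrics`: one-row tibble with columns
#'   `location`, `defined`, `peak_amplitude`, `appearance_time`,
#'   `time_to_peak`, `appearance_to_peak`, `auc`, `mean_transit_time`.
#' @export
curve_metrics <- function(curve, appearance_fraction = 0.05) {
  check_number(appearance_fraction, "appearance_fraction", 0, 1, strict = TRUE)
  tm <- curve$time
  v <- curve$value
  bsd <- attr(curve, "baseline_sd") %||% 0
  loc <- attr(curve, "location") %||% NA_character_
  undefined <- tibble(
    location = loc, defined = FALSE, peak_amplitude = NA_real_,
    appearance_time = NA_real_, time_to_peak = NA_real_,
    appearance_to_peak = NA_real_, auc = NA_real_, mean_transit_time = NA_real_
  )
  class(undefined) <- c("curve_metrics", class(undefined))
  if (all(!is.finite(v))) return(undefined)
  ipk <- which.max(v)
  peak <- v[ipk]
  if (!(peak > 0) || peak <= 3 * bsd) return(undefined)

  thr <- appearance_fraction * peak
  above <- v > thr
  # appearance: first index at/before the peak above threshold with the
  # next frame also above (2-frame persistence)
  app <- NA_integer_
  for (i in seq_len(ipk)) {
    if (above[i] && (i == length(v) || above[i + 1L])) { app <- i; break }
  }
  if (is.na(app)) return(undefined)
  # support end: first return below the appearance level after the peak
  post <- which(!above & seq_along(v) > ipk)
  truncated <- length(post) == 0L
  endi <- if (truncated) length(v) else post[1]

  sup <- app:endi
  auc <- trapz(tm[sup], v[sup])
  m1 <- trapz(tm[sup], tm[sup] * v[sup])
  if (truncated) {
    fit <- fit_gamma_variate(tm[app:length(v)], v[app:length(v)])
    if (!is.null(fit)) {
      # extend on a fine grid until the fitted curve falls below threshold
      dt <- diff(tm[1:2]) / 10
      text_ <- seq(tm[endi] + dt, fit$t0 + fit$tp * 30, by = dt)
      vext <- bolus_concentration(text_, fit$t0, fit$tp, fit$alpha, fit$amp)
      stop_at <- which(vext < thr)
      if (length(stop_at)) text_ <- text_[seq_len(stop_at[1])]
      vext <- bolus_concentration(text_, fit$t0, fit$tp, fit$alpha, fit$amp)
      if (length(text_) > 1) {
        auc <- auc + trapz(text_, vext)
        m1 <- m1 + trapz(text_, text_ * vext)
      }
    }
  }

  out <- tibble(
    location = loc, defined = TRUE, peak_amplitude = peak,
    appearance_time = tm[app], time_to_peak = tm[ipk],
    appearance_to_peak = tm[ipk] - tm[app], auc = auc,
    mean_transit_time = m1 / auc
  )
  class(out) <- c("curve_metrics", class(out))
  out
}

#' Relative regional flow from dilution-curve areas
#'
#' Stewart-Hamilton estimate under a fixed indicator amount per territory:
#' relative flow per region is proportional to 1/AUC, normalized to sum to
#' 1 over the regions with defined metrics. Regions with no signal
#' (occluded territory) are reported as flow 0.
#'
#' @param metrics_by_region A named list of [curve_metrics()] rows, or a
#'   `curve_metrics` tibble with a `region` column.
#' @param injected_amount Injected indicator amount (a.u.); cancels in the
#'   normalization and is kept for bookkeeping only.
#' @return Object of class `flow_estimate`: tibble with `region`, `auc`,
#'   `relative_flow`.
#' @export
estimate_relative_flow <- function(metrics_by_region, injected_amount = NULL) {
  tab <- if (is.data.frame(metrics_by_region)) {
    if (!"region" %in% names(metrics_by_region)) {
      eit_abort("Metrics table needs a `region` column.", "parameter")
    }
    metrics_by_region
  } else {
    dplyr::bind_rows(lapply(names(metrics_by_region), function(r) {
      dplyr::mutate(metrics_by_region[[r]], region = r)
    }))
  }
  if (!nrow(tab)) eit_abort("No regions supplied.", "parameter")
  if (!any(tab$defined)) {
    eit_abort("All regional curves are undefined: no flow can be estimated.", "no_signal")
  }
  w <- ifelse(tab$defined & tab$auc > 0, 1 / tab$auc, 0)
  out <- tibble(region = tab$region, auc = tab$auc,
                relative_flow = w / sum(w))
  structure(out, class = c("flow_estimate", class(out)),
            injected_amount = injected_amount)
}

#' Detect perfusion defects in a perfusion functional image
#'
#' A lung pixel is defect-labelled when its perfusion value falls below
#' `defect_threshold` x (median perfusion value over all lung pixels).
#' Returns the binary defect map and the per-lung defect area fractions.
#'
#' @param perfusion_img A `functional_image` of kind `"perfusion"`.
#' @param lung_masks Named list of logical 32x32 masks, e.g.
#'   `list(right = ..., left = ...)`; must be nonempty.
#' @param defect_threshold Fraction of the lung-median perfusion below
#'   which a pixel counts as defect (default 0.2).
#' @return Object of class `defect_result`: list with `defect_map`
#'   (logical 32x32) and `fractions` (tibble: `lung`, `n_pixels`,
#'   `defect_fraction`).
#' @export
detect_perfusion_defect <- function(perfusion_img, lung_masks, defect_threshold = 0.2) {
  if (!inherits(perfusion_img, "functional_image") ||
      !identical(perfusion_img$kind, "perfusion")) {
    eit_abort("`perfusion_img` must be a perfusion functional image.", "parameter")
  }
  check_number(defect_threshold, "defect_threshold", 0, 1, strict = TRUE)
  if (!length(lung_masks) || !all(vapply(lung_masks, any, TRUE))) {
    eit_abort("`lung_masks` must be nonempty logical masks.", "parameter")
  }
  all_lung <- Reduce(`|`, lung_masks)
  vals <- perfusion_img$pixels[all_lung]
  med <- median(vals)
  if (!is.finite(med) || med <= 0 || max(vals) <= 0) {
    eit_abort("Degenerate perfusion image: no positive lung perfusion signal.",
              "degenerate_input")
  }
  defect_map <- matrix(FALSE, IMG_N, IMG_N)
  defect_map[all_lung] <- perfusion_img$pixels[all_lung] < defect_threshold * med
  fractions <- dplyr::bind_rows(lapply(names(lung_masks), function(nm) {
    m <- lung_masks[[nm]]
    tibble(lung = nm, n_pixels = sum(m),
           defect_fraction = sum(defect_map & m) / sum(m))
  }))
  structure(list(defect_map = defect_map, fractions = fractions,
                 threshold = defect_threshold, lung_median = med),
            class = "defect_result")
}

#' @export
print.defect_result <- function(x, ...) {
  cat("<defect_result>\n")
  print(x$fractions)
  invisible(x)
}
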