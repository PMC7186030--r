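# Functional EIT images: regional ventilation (end-inspiratory minus
# end-expiratory impedance change) and regional perfusion (pre-bolus minus
# full-bolus-arrival impedance change).

#' Segment breaths from a reconstructed image sequence
#'
#' Detects end-inspiration (peaks) and end-expiration (troughs) of the
#' global impedance signal (per-frame sum of in-mask pixel values) with a
#' minimum-separation constraint of half a breath period. Lung inflation
#' raises regional impedance, so the global signal peaks at
#' end-inspiration.
#'
#' @param images An [reconstruct_series()] `impedance_series`.
#' @param breath_rate_hint Expected breath rate in breaths/min (default 12).
#' @return Object of class `breath_segmentation`:
#'   `end_inspiration_indices`, `end_expiration_indices` (frame indices,
#'   alternating in time; every end-inspiration lies between two
#'   end-expirations), `global_signal`, `n_breaths` (complete
#'   expiration-to-expiration cycles).
#' @export
segment_breaths <- function(images, breath_rate_hint = 12) {
  stopifnot(inherits(images, "impedance_series"))
  check_number(breath_rate_hint, "breath_rate_hint", 0, strict = TRUE)
  z <- apply(images$pixels, 3, function(p) sum(p[images$mask]))
  dt <- diff(images$times[1:2])
  min_sep <- max(1L, floor(0.5 * (60 / breath_rate_hint) / dt))
  if (diff(range(z)) == 0) {
    eit_abort("Global signal is constant: no breaths to segment.", "insufficient_signal")
  }
  peaks <- local_extrema(z, min_sep, find_max = TRUE)
  troughs <- local_extrema(z, min_sep, find_max = FALSE)
  # enforce alternation: keep the most extreme point of any same-type run
  typ <- c(rep(1L, length(peaks)), rep(-1L, length(troughs)))
  pos <- c(peaks, troughs)
  o <- order(pos)
  typ <- typ[o]; pos <- pos[o]
  keep <- rep(TRUE, length(pos))
  i <- 1L
  while (i < length(pos)) {
    j <- i + 1L
    while (j <= length(pos) && typ[j] == typ[i]) j <- j + 1L
    if (j - i > 1L) {
      run <- i:(j - 1L)
      best <- run[if (typ[i] == 1L) which.max(z[pos[run]]) else which.min(z[pos[run]])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j
  }
  pos <- pos[keep]; typ <- typ[keep]
  insp <- pos[typ == 1L]
  exp_ <- pos[typ == -1L]
  # complete breaths: end-expiration ... end-inspiration ... end-expiration
  insp <- insp[insp > min(exp_) & insp < max(exp_)]
  n_breaths <- length(insp)
  if (n_breaths < 2L) {
    eit_abort("Fewer than 2 complete breaths detected.", "insufficient_signal")
  }
  structure(
    list(end_inspiration_indices = insp, end_expiration_indices = exp_,
         global_signal = z, n_breaths = n_breaths),
    class = "breath_segmentation"
  )
}

# Local extrema with a +/- min_sep dominance window; series endpoints count
# when they dominate their visible window (so a trough at frame 1 of a
# breath-hold-free record is detected). First index wins within plateaus.
local_extrema <- function(z, min_sep, find_max = TRUE) {
  n <- length(z)
  s <- if (find_max) z else -z
  out <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - min_sep); hi <- min(n, i + min_sep)
    w <- s[lo:hi]
    if (s[i] == max(w) && !any(s[lo:hi][seq_len(i - lo)] == s[i])) {
      out <- c(out, i)
    }
  }
  out
}

#' @export
print.breath_segmentation <- function(x, ...) {
  cat(sprintf("<breath_segmentation> %d complete breaths (%d end-insp, %d end-exp marks)\n",
              x$n_breaths, length(x$end_inspiration_indices),
              length(x$end_expiration_indices)))
  invisible(x)
}

new_functional_image <- function(pixels, mask, kind, metadata) {
  structure(
    list(pixels = pixels, mask = mask, kind = kind, metadata = metadata),
    class = c("functional_image", "impedance_image")
  )
}

#' Functional image of regional ventilation
#'
#' Per pixel, the mean over breaths of (end-inspiratory value minus the
#' preceding end-expiratory value) of the relative impedance change.
#' Ventilated lung regions inflate with poorly conducting air, so their
#' impedance rises at end-inspiration and they appear as large positive
#' values (displayed in light tones).
#'
#' @param images An `impedance_series`.
#' @param segmentation A [segment_breaths()] result, or a list with
#'   `end_inspiration_indices` and `end_expiration_indices` (e.g. nominal
#'   indices for a breath-hold control).
#' @return A `functional_image` of kind `"ventilation"`.
#' @export
ventilation_image <- function(images, segmentation) {
  stopifnot(inherits(images, "impedance_series"))
  insp <- segmentation$end_inspiration_indices
  exp_ <- segmentation$end_expiration_indices
  if (length(insp) < 1L || length(exp_) < 1L) {
    eit_abort("Empty breath segmentation.", "parameter")
  }
  acc <- matrix(0, IMG_N, IMG_N)
  n_used <- 0L
  for (i in insp) {
    prev <- exp_[exp_ < i]
    if (!length(prev)) next
    e <- max(prev)
    acc <- acc + series_frame(images, i) - series_frame(images, e)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) eit_abort("No end-inspiration with preceding end-expiration.", "parameter")
  new_functional_image(acc / n_used, images$mask, "ventilation",
                       list(n_breaths = n_used, end_inspiration = insp,
                            end_expiration = exp_))
}

#' Functional image of regional perfusion
#'
#' Per pixel, (mean over the pre-bolus frames) minus (mean over a 3-frame
#' window centred on the bolus-arrival frame) of the relative impedance
#' change. The conductive bolus lowers impedance on arrival, so perfused
#' regions carry positive values (impedance fall, displayed in light
#' tones).
#'
#' @param images An `impedance_series`.
#' @param pre_bolus_range Integer indices of pre-injection frames; must
#'   wholly precede the arrival window.
#' @param arrival_index Frame index of full bolus arrival (see
#'   [detect_bolus_arrival()]).
#' @param window Half-width of the arrival window in frames (default 1:
#'   3 frames total).
#' @return A `functional_image` of kind `"perfusion"` with the arrival
#'   frame recorded in `metadata`.
#' @export
perfusion_image <- function(images, pre_bolus_range, arrival_index, window = 1L) {
  stopifnot(inherits(images, "impedance_series"))
  nT <- dim(images$pixels)[3]
  pre_bolus_range <- as.integer(pre_bolus_range)
  arrival_index <- as.integer(arrival_index)
  if (any(pre_bolus_range < 1L) || arrival_index > nT) {
    eit_abort("Frame indices out of range.", "index")
  }
  win <- max(1L, arrival_index - window):min(nT, arrival_index + window)
  if (max(pre_bolus_range) >= min(win)) {
    eit_abort("Pre-bolus range must precede the arrival window.", "parameter")
  }
  pre <- apply(images$pixels[, , pre_bolus_range, drop = FALSE], c(1, 2), mean)
  arr <- apply(images$pixels[, , win, drop = FALSE], c(1, 2), mean)
  new_functional_image(pre - arr, images$mask, "perfusion",
                       list(pre_bolus_range = range(pre_bolus_range),
                            arrival_index = arrival_index, window_frames = win))
}

#' Detect the full-bolus-arrival frame
#'
#' Index of the frame minimizing the mean in-ROI pixel value (deepest
#' impedance fall); ties broken by the earliest index. The minimum must be
#' deeper than 3x the pre-injection standard deviation of the ROI signal,
#' otherwise no arrival is declared.
#'
#' @param images An `impedance_series`.
#' @param roi_mask Logical 32x32 region-of-interest mask (nonempty).
#' @param baseline_frames Frames treated as pre-injection when computing
#'   the depth criterion (default: the first 10% of frames, at least 5).
#' @return Integer frame index of the arrival.
#' @export
detect_bolus_arrival <- function(images, roi_mask, baseline_frames = NULL) {
  stopifnot(inherits(images, "impedance_series"))
  if (!is.logical(roi_mask) || !any(roi_mask)) {
    eit_abort("`roi_mask` must be a nonempty logical mask.", "parameter")
  }
  nT <- dim(images$pixels)[3]
  if (is.null(baseline_frames)) baseline_frames <- seq_len(max(5L, nT %/% 10L))
  z <- apply(images$pixels, 3, function(p) mean(p[roi_mask]))
  base_mean <- mean(z[baseline_frames])
  base_sd <- sd(z[baseline_frames])
  k <- which.min(z) # which.min returns the earliest of tied minima
  depth <- base_mean - z[k]
  if (!is.finite(depth) || depth <= 3 * base_sd || depth <= 0) {
    eit_abort("No bolus arrival: ROI minimum is not deeper than 3x the pre-injection SD.",
              "no_arrival")
  }
  as.integer(k)
}
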