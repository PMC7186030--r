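# broom-style tidiers for the result objects.

#' Tidy an impedance or functional image into a pixel tibble
#'
#' @param x An `impedance_image` / `functional_image`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `x`, `y` (unit-disk coordinates),
#'   `value`, `in_disk`.
#' @export
tidy.impedance_image <- function(x, ...) {
  g <- grid_coords(IMG_N)
  vals <- as.vector(x$pixels)
  in_disk <- as.vector(x$mask)
  tibble(
    row = rep(seq_len(IMG_N), IMG_N),
    col = rep(seq_len(IMG_N), each = IMG_N),
    x = as.vector(g$X), y = as.vector(g$Y),
    value = vals,
    in_disk = in_disk
  )
}

#' Tidy a dilution curve
#'
#' @param x A `dilution_curve`.
#' @param ... Unused.
#' @return Tibble with `location`, `time`, `value`.
#' @export
tidy.dilution_curve <- function(x, ...) {
  tibble(location = attr(x, "location") %||% NA_character_,
         time = x$time, value = x$value)
}

#' @export
glance.dilution_curve <- function(x, ...) {
  tibble(location = attr(x, "location") %||% NA_character_,
         n_frames = nrow(x),
         baseline_mean = attr(x, "baseline_mean"),
         baseline_sd = attr(x, "baseline_sd"),
         peak = max(x$value))
}

#' @export
tidy.curve_metrics <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "curve_metrics")
  out
}

#' @export
glance.curve_metrics <- function(x, ...) {
  tibble(n_curves = nrow(x), n_defined = sum(x$defined))
}

#' @export
tidy.flow_estimate <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "flow_estimate")
  out
}

#' @export
glance.flow_estimate <- function(x, ...) {
  tibble(n_regions = nrow(x), n_perfused = sum(x$relative_flow > 0),
         injected_amount = attr(x, "injected_amount") %||% NA_real_)
}

#' @export
tidy.defect_result <- function(x, ...) {
  x$fractions
}

#' @export
tidy.breath_segmentation <- function(x, ...) {
  dplyr::arrange(dplyr::bind_rows(
    tibble(event = "end_inspiration", frame = x$end_inspiration_indices),
    tibble(event = "end_expiration", frame = x$end_expiration_indices)
  ), .data$frame)
}

#' @export
tidy.eit_series <- function(x, ...) {
  nch <- nrow(x$values)
  tibble(
    time = rep(x$times, each = nch),
    channel = rep(seq_len(nch), length(x$times)),
    voltage = as.vector(x$values)
  )
}
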