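# ggplot2 graphics for the result objects. Images are displayed with the
# ventral edge on top and the animal's right on the image left
# (radiological convention); "light tones = large impedance fall" for
# perfusion-type images, matching the PNG renders.

#' @export
autoplot.impedance_image <- function(object, ...) {
  df <- tidy.impedance_image(object)
  df$value[!df$in_disk] <- NA
  lab <- switch(object$kind,
    ventilation = "end-insp - end-exp\nimpedance change",
    perfusion = "impedance fall\non bolus arrival",
    "relative impedance\nchange"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey20", name = lab) +
    ggplot2::labs(x = "column (right → left)", y = "row (ventral → dorsal)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dilution_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "impedance fall [a.u.]",
                  title = attr(object, "location")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flow_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$relative_flow)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative flow (1/AUC, normalized)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.defect_result <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(IMG_N), IMG_N),
    col = rep(seq_len(IMG_N), each = IMG_N),
    defect = as.vector(object$defect_map)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$defect)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85", `TRUE` = "red3"),
                               name = "defect") +
    ggplot2::theme_minimal()
}

#' Plot the global impedance signal with breath marks
#'
#' @param images An `impedance_series`.
#' @param segmentation Optional [segment_breaths()] result; marks
#'   end-inspiration/-expiration frames.
#' @return A ggplot object.
#' @export
plot_global_signal <- function(images, segmentation = NULL) {
  z <- apply(images$pixels, 3, function(p) sum(p[images$mask]))
  df <- tibble(time = images$times, signal = z)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "global in-mask impedance change") +
    ggplot2::theme_minimal()
  if (!is.null(segmentation)) {
    marks <- tidy.breath_segmentation(segmentation)
    marks$time <- images$times[marks$frame]
    marks$signal <- z[marks$frame]
    gg <- gg + ggplot2::geom_point(
      data = marks,
      ggplot2::aes(colour = .data$event), size = 2
    )
  }
  gg
}
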