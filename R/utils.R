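# Internal helpers shared across modules.

eit_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("eitperf_error_", class), "eitperf_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    eit_abort(
      sprintf("`%s` must be a single finite number in %s%s, %s%s.",
              name, if (strict) "(" else "[", lower, upper, if (strict) ")" else "]"),
      "parameter"
    )
  }
  invisible(x)
}

# Trapezoidal rule on possibly non-uniform abscissae.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Cell-centre coordinates of an n x n grid over [-1, 1]^2.
# Convention used everywhere in the package: matrices are indexed [row, col],
# row 1 is the ventral edge (y = +1), column 1 the animal's right (x = -1).
grid_coords <- function(n) {
  h <- 2 / n
  xs <- -1 + (seq_len(n) - 0.5) * h
  ys <- 1 - (seq_len(n) - 0.5) * h
  list(
    h = h, x = xs, y = ys,
    X = matrix(xs, n, n, byrow = TRUE),
    Y = matrix(ys, n, n)
  )
}

disk_mask <- function(n) {
  g <- grid_coords(n)
  g$X^2 + g$Y^2 < 1
}
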