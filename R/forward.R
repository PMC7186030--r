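# Forward problem: boundary voltages of the 16-electrode adjacent-drive
# protocol for a given conductivity field.
#
# The 2D conduction equation div(sigma grad u) = 0 on the unit disk with
# point-electrode Neumann drive (+I at one electrode, -I at the adjacent
# one, zero flux elsewhere) is solved by linear triangular finite elements
# on a polar disk mesh (concentric rings x aligned angular spokes).
# Electrodes sit exactly at boundary mesh nodes at the ideal angles, so no
# electrode-position discretization error enters. Conductivity is sampled
# per element from the Cartesian phantom grid (piecewise constant, value of
# the grid cell containing the element centroid). The Neumann nullspace is
# removed by pinning the central node; all outputs are inter-electrode
# differences and therefore gauge-invariant, and the stiffness matrix is
# symmetric, so reciprocity holds to solver round-off.

#' Electrode layout for the adjacent-drive protocol
#'
#' Sixteen equally spaced point electrodes on the unit-circle boundary.
#' Electrode 1 sits at the ventral midline and numbering increases
#' clockwise when the supine animal is viewed from cranial (a package
#' convention; the measurement protocol itself does not fix the numbering
#' origin or direction).
#'
#' @param n_electrodes Number of electrodes (default 16).
#' @return Object of class `electrode_layout` with `n_electrodes`, `angles`
#'   (radians, standard maths convention, decreasing = clockwise) and
#'   boundary `positions` (x, y on the unit circle).
#' @export
electrode_layout <- function(n_electrodes = 16) {
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes < 4L) eit_abort("Need at least 4 electrodes.", "parameter")
  angles <- pi / 2 - (seq_len(n_electrodes) - 1) * 2 * pi / n_electrodes
  structure(
    list(n_electrodes = n_electrodes, angles = angles,
         positions = cbind(x = cos(angles), y = sin(angles))),
    class = "electrode_layout"
  )
}

#' Adjacent drive/measurement pattern
#'
#' Current is driven consecutively through all 16 adjacent electrode pairs;
#' after each drive, differential voltages are read from all adjacent
#' electrode pairs not containing a driven electrode: 13 measurements per
#' drive, 208 channels per frame. Channels are ordered drive-major, with
#' measurement pairs by increasing electrode index (pair 16 wraps 16 -> 1).
#'
#' @param layout An [electrode_layout()].
#' @return Object of class `drive_pattern` with `drives` (16 x 2 electrode
#'   indices), `measurements` (list of 13 measurement-pair indices per
#'   drive) and a per-channel tibble `channels` (`channel`, `drive`,
#'   `meas_pair`, `meas_a`, `meas_b`).
#' @export
drive_pattern <- function(layout = electrode_layout()) {
  n <- layout$n_electrodes
  nxt <- function(i) i %% n + 1L
  pairs <- cbind(a = seq_len(n), b = nxt(seq_len(n)))
  meas <- lapply(seq_len(n), function(d) {
    setdiff(seq_len(n), c((d - 2L) %% n + 1L, d, nxt(d)))
  })
  channels <- dplyr::bind_rows(lapply(seq_len(n), function(d) {
    tibble(drive = d, meas_pair = meas[[d]],
           meas_a = pairs[meas[[d]], "a"], meas_b = pairs[meas[[d]], "b"])
  }))
  channels$channel <- seq_len(nrow(channels))
  structure(
    list(n_drives = n, drives = pairs, measurements = meas,
         channels = channels[, c("channel", "drive", "meas_pair", "meas_a", "meas_b")]),
    class = "drive_pattern"
  )
}

# Triangular mesh of the unit disk: `rings` concentric rings with `n_ang`
# aligned angular spokes plus a central node. Spoke 1 is at the ventral
# midline so every electrode angle coincides with a boundary node.
disk_mesh <- function(rings = 32, n_ang = 96, layout = electrode_layout()) {
  ne <- layout$n_electrodes
  if (n_ang %% ne != 0) {
    eit_abort("`n_ang` must be a multiple of the electrode count.", "parameter")
  }
  ang <- pi / 2 - (seq_len(n_ang) - 1) * 2 * pi / n_ang
  nodes <- rbind(
    c(0, 0),
    do.call(rbind, lapply(seq_len(rings), function(j) {
      cbind(j / rings * cos(ang), j / rings * sin(ang))
    }))
  )
  id <- function(j, i) as.integer(1 + (j - 1) * n_ang + ((i - 1) %% n_ang + 1))
  i_seq <- seq_len(n_ang)
  tri <- cbind(1L, id(1L, i_seq), id(1L, i_seq + 1L))
  for (j in seq_len(rings - 1L)) {
    tri <- rbind(
      tri,
      cbind(id(j, i_seq), id(j + 1L, i_seq), id(j + 1L, i_seq + 1L)),
      cbind(id(j, i_seq), id(j + 1L, i_seq + 1L), id(j, i_seq + 1L))
    )
  }
  enode <- vapply(seq_len(ne), function(k) id(rings, 1L + (k - 1L) * n_ang %/% ne), 0L)
  centroid <- cbind(
    (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3,
    (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  )
  list(nodes = nodes, tri = tri, enode = enode, rings = rings, n_ang = n_ang,
       centroid = centroid)
}

# Map mesh-element centroids to in-disk cells of an n x n Cartesian grid
# (pulling points radially inward until they land in an in-disk cell).
element_cells <- function(mesh, grid_n) {
  h <- 2 / grid_n
  disk <- disk_mask(grid_n)
  cell_of <- function(p) {
    cc <- pmin(grid_n, pmax(1L, floor((p[, 1] + 1) / h) + 1L))
    rr <- pmin(grid_n, pmax(1L, floor((1 - p[, 2]) / h) + 1L))
    (cc - 1L) * grid_n + rr
  }
  p <- mesh$centroid
  cells <- cell_of(p)
  bad <- which(!disk[cells])
  shrink <- 1
  while (length(bad) && shrink > 0.5) {
    shrink <- shrink - 0.02
    cells[bad] <- cell_of(p[bad, , drop = FALSE] * shrink)
    bad <- bad[!disk[cells[bad]]]
  }
  if (length(bad)) eit_abort("Failed to map mesh elements onto the grid.", "numerical_failure")
  cells
}

# Precomputed FEM machinery for repeated solves with fields on one grid.
# Internal; cached inside solve_forward()/simulate_acquisition().
forward_system <- function(grid_n, layout = electrode_layout(),
                           rings = 32, n_ang = 96) {
  mesh <- disk_mesh(rings, n_ang, layout)
  nd <- mesh$nodes
  tr <- mesh$tri
  x <- matrix(nd[tr, 1], ncol = 3)
  y <- matrix(nd[tr, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  area <- abs((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
                (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])) / 2
  # Element-local stiffness entries (b_a b_b + c_a c_b)/(4A), one column per
  # ordered vertex pair; scaled by sigma_e at assembly time.
  combos <- expand.grid(a = 1:3, bb = 1:3)
  ke <- vapply(seq_len(nrow(combos)), function(m) {
    a <- combos$a[m]; bb <- combos$bb[m]
    (b[, a] * b[, bb] + cc[, a] * cc[, bb]) / (4 * area)
  }, numeric(nrow(tr)))
  tri_i <- as.vector(vapply(combos$a, function(a) tr[, a], integer(nrow(tr))))
  tri_j <- as.vector(vapply(combos$bb, function(a) tr[, a], integer(nrow(tr))))

  pin <- 1L # central node
  keep <- seq_len(nrow(nd))[-pin]
  remap <- integer(nrow(nd)); remap[keep] <- seq_along(keep)
  ok <- tri_i != pin & tri_j != pin
  tri_i2 <- remap[tri_i[ok]]; tri_j2 <- remap[tri_j[ok]]
  ke_flat_idx <- which(ok)

  assemble <- function(sigma_e) {
    vals <- as.vector(sweep(ke, 1, sigma_e, `*`))[ke_flat_idx]
    Matrix::forceSymmetric(Matrix::sparseMatrix(
      i = tri_i2, j = tri_j2, x = vals,
      dims = c(nrow(nd) - 1L, nrow(nd) - 1L)
    ))
  }

  env <- new.env(parent = emptyenv())
  env$chol <- NULL
  list(grid_n = grid_n, layout = layout, mesh = mesh,
       cells = element_cells(mesh, grid_n),
       n_nodes = nrow(nd), area = area, b = b, cc = cc,
       pin = pin, keep = keep, remap = remap, assemble = assemble, cache = env)
}

# Element conductivities from a Cartesian field.
field_to_elements <- function(sys, field) {
  if (!is.matrix(field) || nrow(field) != sys$grid_n || ncol(field) != sys$grid_n) {
    eit_abort(sprintf("`field` must be a %dx%d matrix.", sys$grid_n, sys$grid_n),
              "parameter")
  }
  sigma_e <- field[sys$cells]
  if (anyNA(sigma_e) || any(sigma_e <= 0)) {
    eit_abort("Conductivity must be strictly positive everywhere on the disk.", "field")
  }
  sigma_e
}

# Potentials at the 16 electrode nodes for all adjacent-pair unit
# injections: n_electrodes x n_drives matrix.
solve_all_drives <- function(sys, field, current = 1) {
  sigma_e <- field_to_elements(sys, field)
  A <- sys$assemble(sigma_e)
  ch <- if (is.null(sys$cache$chol)) Matrix::Cholesky(A, LDL = FALSE) else
    Matrix::update(sys$cache$chol, A)
  sys$cache$chol <- ch
  ne <- sys$layout$n_electrodes
  nxt <- function(i) i %% ne + 1L
  B <- matrix(0, sys$n_nodes, ne)
  for (d in seq_len(ne)) {
    B[sys$mesh$enode[d], d] <- B[sys$mesh$enode[d], d] + current
    B[sys$mesh$enode[nxt(d)], d] <- B[sys$mesh$enode[nxt(d)], d] - current
  }
  U <- as.matrix(Matrix::solve(ch, B[sys$keep, , drop = FALSE], system = "A"))
  Ufull <- matrix(0, sys$n_nodes, ne)
  Ufull[sys$keep, ] <- U
  Ufull[sys$mesh$enode, , drop = FALSE]
}

frame_from_ue <- function(ue, pattern) {
  ne <- nrow(ue)
  nxt <- function(i) i %% ne + 1L
  vpairs <- ue - ue[nxt(seq_len(ne)), , drop = FALSE]
  unlist(lapply(seq_len(pattern$n_drives), function(d) {
    vpairs[pattern$measurements[[d]], d]
  }), use.names = FALSE)
}

#' Solve the forward problem for one conductivity field
#'
#' Computes the 208 adjacent differential boundary voltages for a strictly
#' positive conductivity field given on the phantom's Cartesian grid. The
#' drive current is normalized to 1: reconstruction works with normalized
#' voltage differences, so the physical current amplitude is irrelevant.
#'
#' @param field `grid_n` x `grid_n` conductivity matrix (values outside the
#'   disk are ignored and may be `NA`).
#' @param layout An [electrode_layout()].
#' @param pattern A [drive_pattern()].
#' @param system Optional cached solver (attribute `"system"` of a previous
#'   result); reuse it when solving many fields on one grid.
#' @param current_amplitude Drive current in arbitrary units (default 1).
#' @param frame_time Acquisition time stamp in seconds.
#' @return Object of class `voltage_frame`: numeric length-208 `values`
#'   (drive-major channel order), `frame_time`, `current_amplitude`; the
#'   solver cache is attached as attribute `"system"`.
#' @examples
#' ph <- build_phantom(32)
#' vf <- solve_forward(ph$sigma0)
#' length(vf$values)
#' @export
solve_forward <- function(field, layout = electrode_layout(),
                          pattern = drive_pattern(layout), system = NULL,
                          current_amplitude = 1, frame_time = 0) {
  if (!is.matrix(field) || nrow(field) != ncol(field)) {
    eit_abort("`field` must be a square matrix.", "parameter")
  }
  if (is.null(system)) system <- forward_system(nrow(field), layout)
  ue <- solve_all_drives(system, field, current = current_amplitude)
  structure(
    list(values = frame_from_ue(ue, pattern), frame_time = frame_time,
         current_amplitude = current_amplitude),
    class = "voltage_frame", system = system
  )
}

#' Simulate a full EIT acquisition from a conductivity series
#'
#' One voltage frame per measuring cycle at times k * 0.077 s, with
#' optional seeded additive Gaussian electrode noise (standard deviation =
#' `noise_sd` x mean absolute noiseless voltage). Consecutive identical
#' fields (e.g. the pre-bolus breath-hold baseline) are solved once and
#' reused; the output is bit-identical either way.
#'
#' @param series A [simulate_scenario()] result.
#' @param layout,pattern Electrode layout and drive pattern.
#' @param n_cycles Number of cycles to acquire (default: all frames of
#'   `series`); the series must supply a field for every cycle.
#' @param noise_sd Noise level as a fraction of the mean absolute voltage;
#'   defaults to the scenario config's `noise_sd`.
#' @param seed RNG seed for the noise; defaults to the config's `seed`.
#' @param system Optional cached solver from a previous run on this grid.
#' @return Object of class `eit_series`: `values` (208 x n_cycles matrix),
#'   `times`, `dt`, `layout`, `pattern`, `channels` tibble, `provenance`
#'   (the scenario config) and the `noise_sd`/`seed` actually used.
#' @export
simulate_acquisition <- function(series, layout = electrode_layout(),
                                 pattern = drive_pattern(layout),
                                 n_cycles = NULL, noise_sd = NULL, seed = NULL,
                                 system = NULL) {
  stopifnot(inherits(series, "conductivity_series"))
  n_avail <- dim(series$fields)[3]
  if (is.null(n_cycles)) n_cycles <- n_avail
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) eit_abort("`n_cycles` must be >= 1.", "parameter")
  if (n_cycles > n_avail) {
    eit_abort(sprintf("Series has %d frames but %d cycles were requested.",
                      n_avail, n_cycles), "insufficient_data")
  }
  noise_sd <- noise_sd %||% series$config$noise_sd
  seed <- seed %||% series$config$seed

  sys <- system %||% forward_system(series$phantom$grid_n, layout)
  nch <- nrow(pattern$channels)
  V <- matrix(NA_real_, nch, n_cycles)
  prev_field <- NULL
  for (k in seq_len(n_cycles)) {
    f <- series$fields[, , k]
    if (!is.null(prev_field) && identical(f, prev_field)) {
      V[, k] <- V[, k - 1L]
    } else {
      V[, k] <- frame_from_ue(solve_all_drives(sys, f), pattern)
      prev_field <- f
    }
  }

  if (noise_sd > 0) {
    sd_abs <- noise_sd * mean(abs(V))
    V <- V + withr::with_seed(seed, matrix(rnorm(length(V), sd = sd_abs), nch, n_cycles))
  }

  structure(
    list(values = V, times = (seq_len(n_cycles) - 1L) * EIT_DT, dt = EIT_DT,
         layout = layout, pattern = pattern, channels = pattern$channels,
         provenance = series$config, noise_sd = noise_sd, seed = seed),
    class = "eit_series", system = sys
  )
}

#' @export
print.eit_series <- function(x, ...) {
  cat(sprintf("<eit_series> %d channels x %d frames (%.1f s at %.0f frames/s)\n",
              nrow(x$values), ncol(x$values), max(x$times), 1 / x$dt))
  invisible(x)
}
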