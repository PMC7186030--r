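# Normalized-difference reconstruction of 32x32 relative-impedance-change
# tomograms from voltage frames, relative to a reference frame.
#
# Two linear operators are provided:
#  * "backprojection": weighted equipotential-band back-projection in the
#    homogeneous-disk geometry with 3x3 uniform post-smoothing (the classic
#    difference-imaging approach for the adjacent protocol);
#  * "regularized_sensitivity": Tikhonov-regularized pseudo-inverse of the
#    Jacobian of log-voltages w.r.t. log-conductivity about the homogeneous
#    disk, used as an independent cross-check of the back-projection.
#
# Sign convention: the pixel value is the relative impedance change vs the
# reference, so a regional conductivity increase (saline arrival) gives
# negative pixels (impedance fall).
#
# Image orientation: row 1 = ventral, column 1 = animal's right (displayed
# left, radiological convention) — identical to the phantom grids.

IMG_N <- 32L

# Analytic boundary/interior potential of the homogeneous unit disk driven
# by a +1/-1 point-electrode pair on the boundary (Neumann image source).
homogeneous_potential <- function(x, y, pos_src, neg_src) {
  (1 / pi) * (log(sqrt((x - neg_src[1])^2 + (y - neg_src[2])^2)) -
                log(sqrt((x - pos_src[1])^2 + (y - pos_src[2])^2)))
}

# 3x3 uniform in-disk smoothing operator as a sparse pixel x pixel matrix.
smoothing_operator <- function(n, mask) {
  idx <- which(mask)
  rr <- (idx - 1L) %% n + 1L
  cc <- (idx - 1L) %/% n + 1L
  ii <- jj <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= n
    nb <- (c2[ok] - 1L) * n + r2[ok]
    ok2 <- mask[nb]
    ii <- c(ii, idx[ok][ok2])
    jj <- c(jj, nb[ok2])
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n^2, n^2))
  rs <- Matrix::rowSums(S)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% S
}

build_backprojection <- function(layout, pattern, smooth = TRUE) {
  n <- IMG_N
  g <- grid_coords(n)
  mask <- g$X^2 + g$Y^2 < 1
  idx <- which(mask)
  px <- g$X[idx]; py <- g$Y[idx]
  ne <- layout$n_electrodes
  nxt <- function(i) i %% ne + 1L
  nch <- nrow(pattern$channels)
  B <- matrix(0, n^2, nch)
  ch0 <- 0L
  for (d in seq_len(ne)) {
    ps <- layout$positions[d, ]
    ns <- layout$positions[nxt(d), ]
    u_pix <- homogeneous_potential(px, py, ps, ns)
    u_el <- homogeneous_potential(layout$positions[, 1], layout$positions[, 2], ps, ns)
    for (m in pattern$measurements[[d]]) {
      ch0 <- ch0 + 1L
      ua <- u_el[m]; ub <- u_el[nxt(m)]
      band <- u_pix >= min(ua, ub) & u_pix <= max(ua, ub)
      B[idx[band], ch0] <- 1
    }
  }
  w <- rowSums(B)
  w[w == 0] <- 1
  M <- B / w
  if (smooth) M <- as.matrix(smoothing_operator(n, mask) %*% M)
  list(matrix = M, mask = mask)
}

build_sensitivity <- function(layout, pattern, lambda_rel = 1e-3,
                              rings = 24, n_ang = 64) {
  n <- IMG_N
  mask <- disk_mask(n)
  sys <- forward_system(n, layout, rings = rings, n_ang = n_ang)
  hom <- matrix(NA_real_, n, n); hom[mask] <- 1
  ue <- solve_all_drives(sys, hom) # also caches the factorization

  # Nodal potentials for all 16 adjacent-pair injections.
  ne <- layout$n_electrodes
  nxt <- function(i) i %% ne + 1L
  B <- matrix(0, sys$n_nodes, ne)
  for (d in seq_len(ne)) {
    B[sys$mesh$enode[d], d] <- 1
    B[sys$mesh$enode[nxt(d)], d] <- -1
  }
  U <- matrix(0, sys$n_nodes, ne)
  U[sys$keep, ] <- as.matrix(Matrix::solve(sys$cache$chol, B[sys$keep, ], system = "A"))

  # Per-element gradients of each injection field (P1: constant per element).
  tr <- sys$mesh$tri
  gx <- gy <- matrix(0, nrow(tr), ne)
  for (d in seq_len(ne)) {
    ud <- U[, d]
    uu <- matrix(ud[tr], ncol = 3)
    gx[, d] <- rowSums(uu * sys$b) / (2 * sys$area)
    gy[, d] <- rowSums(uu * sys$cc) / (2 * sys$area)
  }

  # dV(d,m)/dsigma_e = -area_e * grad(u_d).grad(u_m); aggregate elements to
  # image pixels and normalize to log-voltage / log-conductivity (sigma = 1).
  chs <- pattern$channels
  nch <- nrow(chs)
  v0 <- frame_from_ue(ue, pattern)
  pix_of_el <- sys$cells
  J <- matrix(0, nch, n^2)
  for (i in seq_len(nch)) {
    d <- chs$drive[i]; m <- chs$meas_pair[i]
    se <- -sys$area * (gx[, d] * gx[, m] + gy[, d] * gy[, m])
    acc <- rowsum(se, pix_of_el)
    J[i, as.integer(rownames(acc))] <- acc[, 1] / v0[i]
  }

  JJt <- tcrossprod(J)
  lambda <- lambda_rel * max(eigen(JJt, symmetric = TRUE, only.values = TRUE)$values)
  # Pixel estimate of delta log sigma; negated so output is impedance change.
  M <- -t(J) %*% solve(JJt + lambda * diag(nch))
  M[!as.vector(mask), ] <- 0
  list(matrix = M, mask = mask, lambda = lambda)
}

#' Build a linear reconstruction operator
#'
#' Maps the 208 normalized channel differences `(V - V_ref)/V_ref` to a
#' 32x32 image of relative impedance change on the unit disk.
#'
#' `"backprojection"` spreads each channel's normalized difference
#' uniformly over the band of pixels between the two equipotential curves
#' of the homogeneous-disk drive field that terminate at the measurement
#' electrodes, takes the weight-normalized sum over channels, and applies a
#' 3x3 uniform in-disk smoothing. `"regularized_sensitivity"` inverts the
#' homogeneous-disk log-sensitivity matrix with Tikhonov regularization
#' (`lambda = lambda_rel` x largest squared singular value) and serves as
#' an independent oracle for the back-projection.
#'
#' @param layout An [electrode_layout()].
#' @param pattern A [drive_pattern()].
#' @param method `"backprojection"` or `"regularized_sensitivity"`.
#' @param lambda_rel Tikhonov parameter relative to the largest squared
#'   singular value of the sensitivity matrix (default 1e-3; sensitivity
#'   method only).
#' @param smooth Apply the 3x3 post-smoothing (back-projection only).
#' @return Object of class `recon_operator` with the 1024 x 208 `matrix`
#'   (rows for out-of-disk pixels all zero), the circular `mask`, `method`
#'   and the `layout`/`pattern` used.
#' @export
build_operator <- function(layout = electrode_layout(),
                           pattern = drive_pattern(layout),
                           method = c("backprojection", "regularized_sensitivity"),
                           lambda_rel = 1e-3, smooth = TRUE) {
  method <- tryCatch(match.arg(method),
                     error = function(e) eit_abort("Unknown reconstruction method.", "parameter"))
  built <- switch(method,
    backprojection = build_backprojection(layout, pattern, smooth = smooth),
    regularized_sensitivity = build_sensitivity(layout, pattern, lambda_rel = lambda_rel)
  )
  structure(
    list(matrix = built$matrix, mask = built$mask, method = method,
         layout = layout, pattern = pattern, lambda = built$lambda),
    class = "recon_operator"
  )
}

#' @export
print.recon_operator <- function(x, ...) {
  cat(sprintf("<recon_operator> %s: %d pixels x %d channels\n",
              x$method, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

new_impedance_image <- function(pixels, mask, reference_id = NA, time = NA_real_,
                                kind = "impedance") {
  structure(
    list(pixels = pixels, mask = mask, reference_id = reference_id,
         time = time, kind = kind),
    class = "impedance_image"
  )
}

#' Reconstruct one relative-impedance-change image
#'
#' Forms normalized channel differences `d = (V - V_ref)/V_ref` and applies
#' the reconstruction operator. A regional conductivity increase (arrival
#' of the conductive saline bolus) yields negative pixel values: an
#' impedance fall relative to the reference state.
#'
#' @param frame A [solve_forward()] voltage frame, or a bare length-208
#'   numeric vector.
#' @param reference Reference frame (same layout/pattern), or numeric
#'   vector; all reference voltages must be nonzero.
#' @param op A [build_operator()] result.
#' @return An `impedance_image`: 32x32 `pixels` matrix (0 outside the
#'   circular support mask), `mask`, `reference_id`, `time`.
#' @export
reconstruct_frame <- function(frame, reference, op) {
  v <- if (inherits(frame, "voltage_frame")) frame$values else as.numeric(frame)
  vr <- if (inherits(reference, "voltage_frame")) reference$values else as.numeric(reference)
  if (length(v) != ncol(op$matrix) || length(vr) != length(v)) {
    eit_abort("Frame/reference length does not match the operator.", "parameter")
  }
  if (any(vr == 0)) eit_abort("Reference frame contains zero voltages.", "degenerate_reference")
  d <- (v - vr) / vr
  pix <- matrix(as.vector(op$matrix %*% d), IMG_N, IMG_N)
  tm <- if (inherits(frame, "voltage_frame")) frame$frame_time else NA_real_
  new_impedance_image(pix, op$mask, reference_id = "explicit", time = tm)
}

#' Reconstruct a whole series against one reference state
#'
#' All frames are reconstructed against the same reference: a single frame
#' index or an index range whose frames are averaged (the usual choice is
#' the mean of all pre-injection frames for bolus runs, or a marked
#' end-expiration frame for ventilation runs).
#'
#' @param series An [simulate_acquisition()] `eit_series`.
#' @param reference Integer vector of frame indices forming the reference
#'   (averaged if more than one).
#' @param op A [build_operator()] result.
#' @return Object of class `impedance_series`: `pixels` (32 x 32 x n_frames
#'   array), `times`, `mask`, `reference` indices, `method`.
#' @export
reconstruct_series <- function(series, reference, op) {
  stopifnot(inherits(series, "eit_series"), inherits(op, "recon_operator"))
  reference <- as.integer(reference)
  nT <- ncol(series$values)
  if (length(reference) < 1L || any(reference < 1L) || any(reference > nT)) {
    eit_abort("Reference indices out of range.", "index")
  }
  vr <- rowMeans(series$values[, reference, drop = FALSE])
  if (any(vr == 0)) eit_abort("Reference frame contains zero voltages.", "degenerate_reference")
  D <- (series$values - vr) / vr
  P <- op$matrix %*% D
  structure(
    list(pixels = array(as.vector(P), c(IMG_N, IMG_N, nT)),
         times = series$times, mask = op$mask, reference = reference,
         method = op$method),
    class = "impedance_series"
  )
}

#' @export
print.impedance_series <- function(x, ...) {
  cat(sprintf("<impedance_series> %d frames of %dx%d (%s), reference = frames %s\n",
              dim(x$pixels)[3], IMG_N, IMG_N, x$method,
              paste(range(x$reference), collapse = ":")))
  invisible(x)
}

# Frame accessor used by the functional/dilution modules.
series_frame <- function(iseries, k) iseries$pixels[, , k]
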