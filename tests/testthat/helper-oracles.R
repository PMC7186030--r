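# Independent closed-form oracles (kept free of package internals).

# Boundary potential of the homogeneous unit disk driven by a +I/-I point
# pair on the boundary: u(theta) = (I/(pi sigma)) *
# ln(|sin((theta - theta_minus)/2)| / |sin((theta - theta_plus)/2)|).
# Returns the 208 adjacent differential voltages in drive-major order.
oracle_adjacent_voltages <- function(current = 1, sigma = 1) {
  th <- pi / 2 - (0:15) * 2 * pi / 16
  nxt <- function(i) i %% 16 + 1
  unlist(lapply(1:16, function(d) {
    th_plus <- th[d]; th_minus <- th[nxt(d)]
    u <- (current / (pi * sigma)) *
      (log(abs(sin((th - th_minus) / 2))) - log(abs(sin((th - th_plus) / 2))))
    v16 <- u - u[nxt(1:16)]
    keep <- setdiff(1:16, c((d - 2) %% 16 + 1, d, d %% 16 + 1))
    v16[keep]
  }))
}

# Gamma-variate analytic facts.
gamma_peak_time <- function(t0, tp) t0 + tp
gamma_mtt_analytic <- function(t0, tp, alpha) t0 + tp * (alpha + 1) / alpha

# Dense-quadrature AUC over the same support rule the package uses
# (appearance-fraction crossing to first return), at step dt/100.
gamma_auc_dense <- function(t0, tp, alpha, amplitude, t_end = 40,
                            frac = 0.05, dt = 0.077 / 100) {
  tt <- seq(0, t_end, by = dt)
  s <- pmax(0, (tt - t0) / tp)
  v <- amplitude * s^alpha * exp(alpha * (1 - s))
  v[tt <= t0] <- 0
  thr <- frac * max(v)
  ipk <- which.max(v)
  app <- which(v > thr & seq_along(v) <= ipk)[1]
  post <- which(v < thr & seq_along(v) > ipk)
  endi <- if (length(post)) post[1] else length(v)
  idx <- app:endi
  sum(diff(tt[idx]) * (head(v[idx], -1) + tail(v[idx], -1)) / 2)
}

# Rising-limb time at which the gamma-variate crosses frac * peak.
gamma_appearance_analytic <- function(t0, tp, alpha, frac = 0.05) {
  f <- function(s) s^alpha * exp(alpha * (1 - s)) - frac
  s <- stats::uniroot(f, c(1e-9, 1))$root
  t0 + tp * s
}
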