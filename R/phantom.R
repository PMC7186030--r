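# Thorax phantom and bolus-injection scenario generator.
#
# The phantom is a 2D transverse thoracic section on the unit disk: two
# air-filled (poorly conducting) lungs, a central blood-rich cardiac region,
# and soft-tissue background. Scenarios evolve the conductivity field in time
# under tidal ventilation and the transit of a hypertonic-saline bolus
# through regional pulmonary vascular compartments.

# Fixed phantom geometry in unit-disk coordinates (+y = ventral):
# lungs at (+/-0.45, -0.05) with semi-axes (0.32, 0.45), heart at
# (0.05, 0.35) with semi-axes (0.22, 0.18). Heart takes precedence where
# the ellipses overlap, so the region masks are disjoint by construction.
PHANTOM_GEOMETRY <- list(
  right_lung = c(cx = -0.45, cy = -0.05, a = 0.32, b = 0.45),
  left_lung  = c(cx =  0.45, cy = -0.05, a = 0.32, b = 0.45),
  heart      = c(cx =  0.05, cy =  0.35, a = 0.22, b = 0.18)
)

#' Build the 2D thorax conductivity phantom
#'
#' Constructs a labelled conductivity map on an `grid_n` x `grid_n` Cartesian
#' grid over the unit disk: two laterally symmetric elliptical lungs, an
#' elliptical cardiac region, and soft-tissue background. Air-filled lung is
#' less conductive than background; the blood-rich heart is more conductive.
#'
#' Matrix convention throughout the package: row 1 is the ventral edge,
#' column 1 the animal's right side (displayed on the image left,
#' radiological convention).
#'
#' @param grid_n Pixels per axis of the simulation grid (>= 32; default 64).
#'   Distinct from the fixed 32x32 reconstruction grid.
#' @param conductivity Named baseline conductivities (arbitrary units) for
#'   `background`, `lung` and `heart`; all must be strictly positive and
#'   `lung` must be below `background`.
#'
#' @return An object of class `thorax_phantom`: a list with `grid_n`, cell
#'   size `h`, axis coordinates `x`/`y`, integer `labels` matrix
#'   (0 = outside disk, 1 = background, 2 = right lung, 3 = left lung,
#'   4 = heart), logical `masks` (`disk`, `right_lung`, `left_lung`,
#'   `heart`), the `conductivity` table and the baseline conductivity
#'   matrix `sigma0` (NA outside the disk).
#'
#' @examples
#' ph <- build_phantom(64)
#' sum(ph$masks$right_lung & ph$masks$heart) # disjoint regions
#' @export
build_phantom <- function(grid_n = 64,
                          conductivity = c(background = 1, lung = 0.35, heart = 1.5)) {
  if (!is.numeric(grid_n) || length(grid_n) != 1L || !is.finite(grid_n) || grid_n < 32) {
    eit_abort("`grid_n` must be a single integer >= 32.", "parameter")
  }
  grid_n <- as.integer(grid_n)
  need <- c("background", "lung", "heart")
  if (!all(need %in% names(conductivity)) || any(conductivity[need] <= 0)) {
    eit_abort("`conductivity` needs strictly positive 'background', 'lung', 'heart'.",
              "parameter")
  }
  if (conductivity[["lung"]] >= conductivity[["background"]]) {
    eit_abort("Air-filled lung must be less conductive than background.", "parameter")
  }

  g <- grid_coords(grid_n)
  disk <- g$X^2 + g$Y^2 < 1
  in_ellipse <- function(p) {
    ((g$X - p[["cx"]]) / p[["a"]])^2 + ((g$Y - p[["cy"]]) / p[["b"]])^2 <= 1
  }
  heart <- in_ellipse(PHANTOM_GEOMETRY$heart) & disk
  right_lung <- in_ellipse(PHANTOM_GEOMETRY$right_lung) & disk & !heart
  left_lung <- in_ellipse(PHANTOM_GEOMETRY$left_lung) & disk & !heart

  labels <- matrix(0L, grid_n, grid_n)
  labels[disk] <- 1L
  labels[right_lung] <- 2L
  labels[left_lung] <- 3L
  labels[heart] <- 4L

  sigma0 <- matrix(NA_real_, grid_n, grid_n)
  sigma0[disk] <- conductivity[["background"]]
  sigma0[right_lung | left_lung] <- conductivity[["lung"]]
  sigma0[heart] <- conductivity[["heart"]]

  structure(
    list(
      grid_n = grid_n, h = g$h, x = g$x, y = g$y,
      labels = labels,
      masks = list(disk = disk, right_lung = right_lung,
                   left_lung = left_lung, heart = heart),
      conductivity = conductivity[need],
      sigma0 = sigma0
    ),
    class = "thorax_phantom"
  )
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat(sprintf("<thorax_phantom> %dx%d grid, %d pixels in disk\n",
              x$grid_n, x$grid_n, sum(x$masks$disk)))
  af <- vapply(x$masks[c("right_lung", "left_lung", "heart")], sum, 0L) / sum(x$masks$disk)
  cat(sprintf("  area fractions: right lung %.3f, left lung %.3f, heart %.3f\n",
              af[1], af[2], af[3]))
  invisible(x)
}

#' Gamma-variate indicator-dilution bolus curve
#'
#' Standard first-pass tracer kinetics: zero before the arrival time `t0`,
#' then `amplitude * ((t - t0)/tp)^alpha * exp(alpha * (1 - (t - t0)/tp))`.
#' The maximum equals `amplitude` and is attained at `t0 + tp`.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param t0 Arrival (appearance) time in seconds.
#' @param tp Time from arrival to peak in seconds (> 0).
#' @param alpha Dimensionless shape parameter (> 0).
#' @param amplitude Peak concentration in arbitrary units (>= 0).
#' @return Concentration at `t`, same length as `t`.
#' @examples
#' bolus_concentration(6, t0 = 2, tp = 4, alpha = 3) # == 1, the peak
#' @export
bolus_concentration <- function(t, t0 = 0, tp = 4, alpha = 3, amplitude = 1) {
  check_number(tp, "tp", lower = 0, strict = TRUE)
  check_number(alpha, "alpha", lower = 0, strict = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  s <- (t - t0) / tp
  out <- numeric(length(t))
  pos <- is.finite(s) & s > 0
  out[pos] <- amplitude * s[pos]^alpha * exp(alpha * (1 - s[pos]))
  out
}

# Analytic integral of the gamma-variate over (t0, Inf).
gamma_variate_auc <- function(tp, alpha, amplitude) {
  amplitude * tp * exp(alpha) * gamma(alpha + 1) / alpha^(alpha + 1)
}

#' Configure a bolus-injection / ventilation scenario
#'
#' Encodes one experimental condition of the protocol: undisturbed
#' mechanical ventilation, or a saline bolus given through the distal
#' catheter opening (reaching only the catheter-side branch territory),
#' through the proximal opening with the balloon inflated (occluding that
#' territory), or through the proximal opening with the balloon deflated
#' (reaching both lungs and the heart). Bolus scenarios are acquired during
#' a breath hold at end-expiration.
#'
#' @param scenario One of `"ventilation_only"`, `"distal"`,
#'   `"proximal_inflated"`, `"proximal_deflated"`.
#' @param catheter_side `"left"` or `"right"`: the pulmonary-artery branch
#'   holding the catheter tip.
#' @param occluded_fraction Fraction of the ipsilateral lung supplied by the
#'   catheterised branch (dorsal-most pixels by y-rank), in (0, 1).
#'   Must not be supplied for `ventilation_only`.
#' @param bolus_volume_ml Bolus volume; fixed by the protocol at 15 ml for
#'   distal and 20 ml for proximal injections.
#' @param bolus_conductivity_gain Peak relative conductivity increase in a
#'   fully perfused reference region (flow fraction 0.5, 20 ml bolus);
#'   default 0.3.
#' @param flow_split Named relative pulmonary blood flow per lung,
#'   `c(right = , left = )`; non-negative, summing to 1.
#' @param breath_rate_per_min Ventilation rate (default 12 breaths/min).
#' @param breath_hold Freeze ventilation at its end-expiratory value;
#'   defaults to `TRUE` for bolus scenarios and `FALSE` for
#'   `ventilation_only`.
#' @param ventilation_conductivity_amplitude Fractional lung-conductivity
#'   decrease at end-inspiration (default 0.2).
#' @param seed Integer RNG seed used for measurement noise downstream.
#' @param noise_sd Additive Gaussian measurement-noise SD as a fraction of
#'   the mean absolute voltage (default 0, applied at the electrodes).
#' @param injection_time_s Time of bolus injection into the record (s).
#' @param bolus_tp,bolus_alpha Gamma-variate kinetics shared by all regions.
#' @param delay_distal_s,delay_heart_s,delay_lung_s Arrival delays after
#'   injection for the distal territory, the cardiac region, and the lungs
#'   under proximal injection (path length ordering: heart before lungs).
#'
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' scenario_config("distal", catheter_side = "left")
#' @export
scenario_config <- function(scenario = c("ventilation_only", "distal",
                                         "proximal_inflated", "proximal_deflated"),
                            catheter_side = c("left", "right"),
                            occluded_fraction = 0.4,
                            bolus_volume_ml = NULL,
                            bolus_conductivity_gain = 0.3,
                            flow_split = c(right = 0.5, left = 0.5),
                            breath_rate_per_min = 12,
                            breath_hold = NULL,
                            ventilation_conductivity_amplitude = 0.2,
                            seed = 1L,
                            noise_sd = 0,
                            injection_time_s = 5,
                            bolus_tp = 4,
                            bolus_alpha = 3,
                            delay_distal_s = 2,
                            delay_heart_s = 1,
                            delay_lung_s = 3) {
  scenario <- match.arg(scenario)
  catheter_side <- match.arg(catheter_side)
  is_bolus <- scenario != "ventilation_only"

  if (!is_bolus && !missing(occluded_fraction)) {
    eit_abort("`occluded_fraction` is meaningless for a ventilation-only run.", "config")
  }
  check_number(occluded_fraction, "occluded_fraction", 0, 1, strict = TRUE)

  required_volume <- switch(scenario,
    distal = 15, proximal_inflated = 20, proximal_deflated = 20,
    ventilation_only = NA_real_
  )
  if (!is_bolus && !is.null(bolus_volume_ml)) {
    eit_abort("`bolus_volume_ml` is meaningless for a ventilation-only run.", "config")
  }
  if (is.null(bolus_volume_ml)) bolus_volume_ml <- required_volume
  if (is_bolus && !isTRUE(bolus_volume_ml == required_volume)) {
    eit_abort(sprintf("The protocol fixes the bolus volume at %g ml for '%s'.",
                      required_volume, scenario), "config")
  }

  if (!is.numeric(flow_split) || length(flow_split) != 2L ||
      !all(c("right", "left") %in% names(flow_split)) ||
      any(flow_split < 0) || abs(sum(flow_split) - 1) > 1e-8) {
    eit_abort("`flow_split` must be named c(right=, left=), non-negative, summing to 1.",
              "config")
  }
  check_number(bolus_conductivity_gain, "bolus_conductivity_gain", 0)
  check_number(breath_rate_per_min, "breath_rate_per_min", 0, strict = TRUE)
  check_number(ventilation_conductivity_amplitude,
               "ventilation_conductivity_amplitude", 0, 1)
  check_number(noise_sd, "noise_sd", 0)
  check_number(injection_time_s, "injection_time_s", 0)
  if (is.null(breath_hold)) breath_hold <- is_bolus

  structure(
    list(
      scenario = scenario,
      catheter_side = catheter_side,
      occluded_fraction = occluded_fraction,
      bolus_volume_ml = bolus_volume_ml,
      bolus_conductivity_gain = bolus_conductivity_gain,
      flow_split = flow_split[c("right", "left")],
      breath_rate_per_min = breath_rate_per_min,
      breath_hold = isTRUE(breath_hold),
      ventilation_conductivity_amplitude = ventilation_conductivity_amplitude,
      seed = as.integer(seed),
      noise_sd = noise_sd,
      injection_time_s = injection_time_s,
      bolus_tp = bolus_tp,
      bolus_alpha = bolus_alpha,
      delay_distal_s = delay_distal_s,
      delay_heart_s = delay_heart_s,
      delay_lung_s = delay_lung_s
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s (catheter %s)\n", x$scenario, x$catheter_side))
  if (x$scenario != "ventilation_only") {
    cat(sprintf("  bolus %g ml, gain %.2f, flow split R/L = %.2f/%.2f, occluded fraction %.2f\n",
                x$bolus_volume_ml, x$bolus_conductivity_gain,
                x$flow_split[["right"]], x$flow_split[["left"]], x$occluded_fraction))
  }
  cat(sprintf("  breath %s at %g/min, noise_sd %g, seed %d\n",
              if (x$breath_hold) "hold" else "tidal", x$breath_rate_per_min,
              x$noise_sd, x$seed))
  invisible(x)
}

#' Dorsal branch territory of one lung
#'
#' The sub-region of a lung supplied by the catheterised arterial branch is
#' modelled as the dorsal-most `fraction` of that lung's pixels ranked by
#' the ventro-dorsal coordinate (ties broken by lateral position, then row
#' order, so the mask is deterministic at any grid size).
#'
#' @param phantom A [build_phantom()] result.
#' @param side `"left"` or `"right"` lung.
#' @param fraction Fraction of the lung's pixels in the territory, in (0,1).
#' @return Logical `grid_n` x `grid_n` mask.
#' @export
territory_mask <- function(phantom, side = c("left", "right"), fraction = 0.4) {
  side <- match.arg(side)
  check_number(fraction, "fraction", 0, 1, strict = TRUE)
  lung <- phantom$masks[[paste0(side, "_lung")]]
  idx <- which(lung)
  g <- grid_coords(phantom$grid_n)
  ord <- order(g$Y[idx], abs(g$X[idx]), idx) # most dorsal (smallest y) first
  keep <- idx[ord][seq_len(round(fraction * length(idx)))]
  out <- matrix(FALSE, phantom$grid_n, phantom$grid_n)
  out[keep] <- TRUE
  out
}

# Regional compartments, flows and bolus kinetics for one scenario.
# Regional curve amplitudes follow Stewart-Hamilton with a fixed injected
# amount per territory: amplitude = gain * (volume/20) * (0.5/flow_fraction),
# so the regional AUC is inversely proportional to regional flow and equals
# gain-scaled m/F. The cardiac region sees the whole output (flow fraction 1).
scenario_regions <- function(phantom, config) {
  sc <- config$scenario
  if (sc == "ventilation_only") {
    return(list(
      table = tibble(region = character(), role = character(),
                     flow_fraction = numeric(), amplitude = numeric(),
                     t0 = numeric()),
      masks = list()
    ))
  }
  side <- config$catheter_side
  other <- if (side == "left") "right" else "left"
  ff <- config$flow_split
  of <- config$occluded_fraction
  gain <- config$bolus_conductivity_gain * config$bolus_volume_ml / 20
  amp <- function(f) if (f > 0) gain * 0.5 / f else 0

  terr <- territory_mask(phantom, side, of)
  ipsi_rest <- phantom$masks[[paste0(side, "_lung")]] & !terr
  contra <- phantom$masks[[paste0(other, "_lung")]]
  heart <- phantom$masks$heart
  terr_name <- paste0(side, "_territory")
  rest_name <- paste0(side, "_rest")

  if (sc == "distal") {
    f_terr <- of * ff[[side]]
    tab <- tibble(
      region = c(terr_name, rest_name, paste0(other, "_lung")),
      role = c("ipsilateral_territory", "ipsilateral_rest", "contralateral"),
      flow_fraction = c(f_terr, (1 - of) * ff[[side]], ff[[other]]),
      amplitude = c(amp(f_terr), 0, 0),
      t0 = c(config$delay_distal_s, NA, NA)
    )
    masks <- setNames(list(terr, ipsi_rest, contra), tab$region)
  } else if (sc == "proximal_inflated") {
    # Balloon occlusion: territory flow interrupted; remaining pulmonary
    # flow renormalised over the open lung regions.
    open <- 1 - of * ff[[side]]
    f_rest <- (1 - of) * ff[[side]] / open
    f_contra <- ff[[other]] / open
    tab <- tibble(
      region = c("heart", terr_name, rest_name, paste0(other, "_lung")),
      role = c("heart", "ipsilateral_territory", "ipsilateral_rest", "contralateral"),
      flow_fraction = c(1, 0, f_rest, f_contra),
      amplitude = c(amp(1), 0, amp(f_rest), amp(f_contra)),
      t0 = c(config$delay_heart_s, NA, config$delay_lung_s, config$delay_lung_s)
    )
    masks <- setNames(list(heart, terr, ipsi_rest, contra), tab$region)
  } else { # proximal_deflated
    tab <- tibble(
      region = c("heart", paste0(side, "_lung"), paste0(other, "_lung")),
      role = c("heart", "ipsilateral", "contralateral"),
      flow_fraction = c(1, ff[[side]], ff[[other]]),
      amplitude = c(amp(1), amp(ff[[side]]), amp(ff[[other]])),
      t0 = c(config$delay_heart_s, config$delay_lung_s, config$delay_lung_s)
    )
    masks <- setNames(
      list(heart, phantom$masks[[paste0(side, "_lung")]], contra),
      tab$region
    )
  }
  tab$auc <- ifelse(
    tab$amplitude > 0,
    gamma_variate_auc(config$bolus_tp, config$bolus_alpha, tab$amplitude),
    0
  )
  list(table = tab, masks = masks)
}

# Ventilation term: fractional lung-conductivity decrease, 0 at
# end-expiration (t = 0), maximal at end-inspiration (mid-breath).
ventilation_term <- function(t, config) {
  if (config$breath_hold) return(numeric(length(t)) )
  f <- config$breath_rate_per_min / 60
  config$ventilation_conductivity_amplitude * (1 - cos(2 * pi * f * t)) / 2
}

#' Simulate the time-resolved conductivity field for one scenario
#'
#' Evolves the phantom conductivity over `n_frames` EIT cycles (77 ms each):
#' per frame, conductivity = baseline x (1 - ventilation term on lung
#' pixels) x (1 + regional bolus concentration). The conductive saline
#' bolus increases conductivity in each perfused compartment following a
#' gamma-variate dilution curve whose area is inversely proportional to the
#' compartment's blood flow (fixed injected amount per territory); in the
#' balloon-occluded territory the concentration is identically zero. Ground
#' truth (regional flows, amplitudes, concentration curves, masks) is
#' stored alongside the fields.
#'
#' The generator itself is fully deterministic; measurement noise enters
#' only at the electrodes in [simulate_acquisition()].
#'
#' @param phantom A [build_phantom()] result.
#' @param config A [scenario_config()].
#' @param n_frames Number of 77-ms frames to generate (default 400, 30.8 s;
#'   the full protocol measurement is 1000 frames = 77 s).
#' @return An object of class `conductivity_series`: list with `phantom`,
#'   `config`, `times` (seconds, frame k at (k-1)*0.077), `fields`
#'   (grid_n x grid_n x n_frames array, NA outside the disk) and `truth`
#'   (list: `regions` tibble with flow fractions/amplitudes/arrival
#'   delays/analytic AUCs, `curves` tibble of regional concentration over
#'   time, `masks` named list).
#' @examples
#' ph <- build_phantom(32)
#' ser <- simulate_scenario(ph, scenario_config("distal"), n_frames = 10)
#' dim(ser$fields)
#' @export
simulate_scenario <- function(phantom, config, n_frames = 400) {
  stopifnot(inherits(phantom, "thorax_phantom"), inherits(config, "scenario_config"))
  if (!is.numeric(n_frames) || n_frames < 1) {
    eit_abort("`n_frames` must be >= 1.", "parameter")
  }
  n_frames <- as.integer(n_frames)
  times <- (seq_len(n_frames) - 1L) * EIT_DT

  reg <- scenario_regions(phantom, config)
  vent <- ventilation_term(times, config)
  lung <- phantom$masks$right_lung | phantom$masks$left_lung

  conc <- vapply(seq_len(nrow(reg$table)), function(i) {
    r <- reg$table[i, ]
    if (r$amplitude <= 0 || is.na(r$t0)) return(numeric(n_frames))
    bolus_concentration(times, t0 = config$injection_time_s + r$t0,
                        tp = config$bolus_tp, alpha = config$bolus_alpha,
                        amplitude = r$amplitude)
  }, numeric(n_frames))
  if (nrow(reg$table)) colnames(conc) <- reg$table$region

  n <- phantom$grid_n
  fields <- array(NA_real_, c(n, n, n_frames))
  for (k in seq_len(n_frames)) {
    f <- phantom$sigma0
    if (vent[k] > 0) f[lung] <- f[lung] * (1 - vent[k])
    for (i in seq_len(nrow(reg$table))) {
      ck <- conc[k, i]
      if (ck > 0) {
        m <- reg$masks[[reg$table$region[i]]]
        f[m] <- f[m] * (1 + ck)
      }
    }
    fields[, , k] <- f
  }

  curves <- if (nrow(reg$table)) {
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble(time = times), as_tibble(conc)),
      -"time", names_to = "region", values_to = "concentration"
    )
  } else {
    tibble(time = numeric(), region = character(), concentration = numeric())
  }

  structure(
    list(phantom = phantom, config = config, times = times, fields = fields,
         truth = list(regions = reg$table, curves = curves, masks = reg$masks)),
    class = "conductivity_series"
  )
}

#' @export
print.conductivity_series <- function(x, ...) {
  cat(sprintf("<conductivity_series> %s: %d frames (%.1f s) on %dx%d grid\n",
              x$config$scenario, length(x$times), max(x$times),
              x$phantom$grid_n, x$phantom$grid_n))
  invisible(x)
}
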