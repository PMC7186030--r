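# Shared, memoized fixtures. Heavy objects (operators, forward systems,
# scenario acquisitions) are built once and reused across test files.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fx_cache)
  }
  get(key, envir = .fx_cache, inherits = FALSE)
}

fx_layout <- function() cached("layout", electrode_layout())
fx_pattern <- function() cached("pattern", drive_pattern(fx_layout()))
fx_phantom <- function(n = 64) cached(paste0("phantom", n), build_phantom(n))
fx_system <- function(n = 64) {
  cached(paste0("system", n), eitperf:::forward_system(n, fx_layout()))
}
fx_op <- function(method = "backprojection") {
  cached(paste0("op_", method), build_operator(fx_layout(), fx_pattern(), method))
}
fx_hom_frame <- function(n = 64) {
  cached(paste0("hom", n),
         solve_forward(matrix(1, n, n), fx_layout(), fx_pattern(),
                       system = fx_system(n)))
}

# Noiseless acquisition of one scenario, memoized by its defining knobs.
fx_acquisition <- function(scenario, n_frames = 400, catheter_side = "left",
                           occluded_fraction = 0.4,
                           flow_split = c(right = 0.5, left = 0.5), ...) {
  key <- paste("acq", scenario, n_frames, catheter_side, occluded_fraction,
               paste(signif(flow_split, 6), collapse = "_"),
               paste(deparse(list(...)), collapse = ""), sep = "|")
  cached(key, {
    cfg <- if (scenario == "ventilation_only") {
      scenario_config(scenario, ...)
    } else {
      scenario_config(scenario, catheter_side = catheter_side,
                      occluded_fraction = occluded_fraction,
                      flow_split = flow_split, ...)
    }
    ser <- simulate_scenario(fx_phantom(), cfg, n_frames = n_frames)
    acq <- simulate_acquisition(ser, fx_layout(), fx_pattern(),
                                noise_sd = 0, system = fx_system())
    list(config = cfg, series = ser, acquisition = acq)
  })
}

# Add seeded electrode noise to a noiseless acquisition (cheap per seed).
with_noise <- function(acq, noise_sd, seed) {
  if (noise_sd <= 0) return(acq)
  V <- acq$values
  sd_abs <- noise_sd * mean(abs(V))
  V <- V + withr::with_seed(seed, matrix(rnorm(length(V), sd = sd_abs),
                                         nrow(V), ncol(V)))
  out <- acq
  out$values <- V
  out$noise_sd <- noise_sd
  out$seed <- seed
  out
}

injection_frame_of <- function(cfg) floor(cfg$injection_time_s / 0.077) + 1L

disk_mask_32 <- function() eitperf:::disk_mask(32)
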