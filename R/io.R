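# Readers/writers: CSV payloads with YAML sidecars, PNG renders, run
# manifests. CSV dialect: comma-separated, '.' decimal, mandatory header
# row, UTF-8. Numeric payloads are written with 17 significant digits so
# that read(write(x)) round-trips doubles exactly.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", out)
}

write_csv_exact <- function(df, path) {
  chr <- vapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else {
      s <- as.character(col)
      needs_quote <- grepl("[,\"]", s)
      s[needs_quote] <- paste0('"', gsub('"', '""', s[needs_quote]), '"')
      s
    }
  }, character(nrow(df)))
  if (nrow(df) == 1L) chr <- matrix(chr, nrow = 1)
  lines <- c(paste(names(df), collapse = ","),
             apply(chr, 1, paste, collapse = ","))
  writeLines(lines, path)
}

# Strict CSV reader: uniform field counts, numeric payload; errors name the
# file and first offending line.
read_csv_strict <- function(path, expect_cols = NULL) {
  if (!file.exists(path)) eit_abort(sprintf("File not found: %s", path), "parse")
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    eit_abort(sprintf("%s: line %d has %d fields, expected %d.",
                      path, bad, nf[bad], nf[1]), "parse")
  }
  df <- read.csv(path, check.names = FALSE)
  if (!is.null(expect_cols) && ncol(df) != expect_cols) {
    eit_abort(sprintf("%s: expected %d columns, found %d.", path, expect_cols, ncol(df)),
              "parse")
  }
  df
}

#' Write / read an EIT voltage series
#'
#' `voltages.csv` holds one row per frame (`time` + 208 channel columns,
#' full double precision); `series.yaml` records the acquisition metadata
#' (dt, noise level, seed, electrode count, per-channel drive/measurement
#' electrodes, scenario provenance).
#'
#' @param x An `eit_series`.
#' @param dir Directory (created if needed).
#' @return `write_eit_series()` returns `dir` invisibly;
#'   `read_eit_series()` returns the reconstructed `eit_series`.
#' @export
write_eit_series <- function(x, dir) {
  stopifnot(inherits(x, "eit_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(time = x$times, t(x$values), check.names = FALSE)
  names(df) <- c("time", sprintf("ch%03d", seq_len(nrow(x$values))))
  write_csv_exact(df, file.path(dir, "voltages.csv"))
  meta <- list(
    dt = x$dt, n_frames = ncol(x$values), n_channels = nrow(x$values),
    n_electrodes = x$layout$n_electrodes,
    noise_sd = x$noise_sd, seed = x$seed,
    channels = lapply(seq_len(nrow(x$channels)), function(i) {
      as.list(x$channels[i, c("drive", "meas_a", "meas_b")])
    }),
    provenance = config_to_list(x$provenance)
  )
  yaml::write_yaml(meta, file.path(dir, "series.yaml"))
  invisible(dir)
}

#' @rdname write_eit_series
#' @export
read_eit_series <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "series.yaml"))
  df <- read_csv_strict(file.path(dir, "voltages.csv"),
                        expect_cols = meta$n_channels + 1L)
  layout <- electrode_layout(meta$n_electrodes)
  pattern <- drive_pattern(layout)
  values <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(values) <- NULL
  structure(
    list(values = values,
         times = df$time, dt = meta$dt, layout = layout, pattern = pattern,
         channels = pattern$channels,
         provenance = if (!is.null(meta$provenance)) config_from_list(meta$provenance),
         noise_sd = meta$noise_sd, seed = meta$seed),
    class = "eit_series"
  )
}

config_to_list <- function(config) {
  if (is.null(config)) return(NULL)
  out <- unclass(config)
  out$flow_split <- as.list(out$flow_split)
  out
}

config_from_list <- function(lst) {
  args <- lst
  args$flow_split <- unlist(lst$flow_split)
  base <- list(scenario = args$scenario)
  keep <- intersect(names(args), setdiff(names(formals(scenario_config)), "scenario"))
  cfg <- do.call(scenario_config, c(base, args[setdiff(keep, c(
    if (args$scenario == "ventilation_only") c("occluded_fraction", "bolus_volume_ml")
  ))]))
  cfg
}

#' Write / read a scenario configuration as YAML
#'
#' @param config A [scenario_config()].
#' @param path YAML file path.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

#' Write / read a 32x32 image as CSV (plus optional PNG and sidecar)
#'
#' The CSV is a 32-row grid with header `c01..c32`; row 1 is ventral,
#' column 1 the animal's right (displayed left, radiological convention).
#' For functional images a YAML sidecar records the kind and frame
#' provenance, and a PNG render is written next to the CSV.
#'
#' @param img An `impedance_image` or `functional_image`.
#' @param path CSV path; sidecars replace the extension by `.yaml`/`.png`.
#' @param png Also write the PNG render (default TRUE for functional
#'   images).
#' @return `write_image()` returns `path` invisibly; `read_image()` the
#'   image object.
#' @export
write_image <- function(img, path, png = inherits(img, "functional_image")) {
  stopifnot(inherits(img, "impedance_image"))
  df <- as.data.frame(img$pixels)
  names(df) <- sprintf("c%02d", seq_len(IMG_N))
  write_csv_exact(df, path)
  side <- sub("\\.[^.]+$", ".yaml", path)
  yaml::write_yaml(list(kind = img$kind,
                        orientation = "row 1 = ventral, column 1 = animal's right",
                        metadata = rapply(img$metadata %||% list(), as.vector, how = "list")),
                   side)
  if (png) write_image_png(img, sub("\\.[^.]+$", ".png", path))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  df <- read_csv_strict(path, expect_cols = IMG_N)
  pix <- as.matrix(df)
  dimnames(pix) <- NULL
  if (nrow(pix) != IMG_N) {
    eit_abort(sprintf("%s: expected %d rows, found %d.", path, IMG_N, nrow(pix)), "parse")
  }
  side <- sub("\\.[^.]+$", ".yaml", path)
  kind <- if (file.exists(side)) yaml::read_yaml(side)$kind else "impedance"
  img <- new_impedance_image(pix, disk_mask(IMG_N), kind = kind %||% "impedance")
  if (!identical(kind, "impedance") && !is.null(kind)) {
    img <- new_functional_image(pix, disk_mask(IMG_N), kind,
                                if (file.exists(side)) yaml::read_yaml(side)$metadata)
  }
  img
}

#' Grayscale rendering of an image
#'
#' Linear grayscale of the "impedance fall" signal: 0 maps to black, the
#' 99th percentile of positive in-disk values to white; negatives are
#' clipped, out-of-disk pixels are black. For raw impedance images the
#' sign is flipped first so that a large impedance fall (bolus arrival) is
#' light, matching the display convention for the functional images.
#'
#' @param img An `impedance_image`/`functional_image`.
#' @return Numeric 32x32 matrix in `[0, 1]`.
#' @export
render_image <- function(img) {
  v <- img$pixels
  if (identical(img$kind, "impedance")) v <- -v
  v[!img$mask] <- 0
  v <- pmax(v, 0)
  hi <- stats::quantile(v[img$mask], 0.99)
  if (hi <= 0) return(matrix(0, IMG_N, IMG_N))
  pmin(v / hi, 1)
}

#' @rdname render_image
#' @param path PNG file path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(render_image(img), path)
  invisible(path)
}

#' Write / read dilution curves and metrics as tidy CSV
#'
#' Curves: one row per location per frame (`location`, `time`, `value`).
#' Metrics: one row per location.
#'
#' @param curves A `dilution_curve` or named list of them.
#' @param path CSV path.
#' @export
write_dilution_curves <- function(curves, path) {
  if (inherits(curves, "dilution_curve")) curves <- list(curves)
  rows <- dplyr::bind_rows(lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    nm <- names(curves)[i] %||% attr(cv, "location") %||% as.character(i)
    tibble(location = nm, time = cv$time, value = cv$value)
  }))
  write_csv_exact(rows, path)
  invisible(path)
}

#' @rdname write_dilution_curves
#' @export
read_dilution_curves <- function(path) {
  df <- read_csv_strict(path, expect_cols = 3L)
  as_tibble(df)
}

#' @rdname write_dilution_curves
#' @param metrics A `curve_metrics` tibble.
#' @export
write_curve_metrics <- function(metrics, path) {
  write_csv_exact(as.data.frame(metrics), path)
  invisible(path)
}

#' Write / read a conductivity series as per-frame CSV grids + manifest
#'
#' Each frame becomes `frame_000k.csv` (a `grid_n` x `grid_n` grid, `NA`
#' outside the disk); `series.yaml` stores times and the scenario
#' configuration, and the ground-truth regional curves go to
#' `truth_curves.csv`. Intended for small excerpts; scenario fields are
#' cheap to regenerate deterministically from the configuration.
#'
#' @param series A `conductivity_series`.
#' @param dir Output directory.
#' @export
write_conductivity_series <- function(series, dir) {
  stopifnot(inherits(series, "conductivity_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- series$phantom$grid_n
  for (k in seq_along(series$times)) {
    df <- as.data.frame(series$fields[, , k])
    names(df) <- sprintf("c%02d", seq_len(n))
    write_csv_exact(df, file.path(dir, sprintf("frame_%04d.csv", k)))
  }
  yaml::write_yaml(list(times = series$times, grid_n = n,
                        config = config_to_list(series$config)),
                   file.path(dir, "series.yaml"))
  write_csv_exact(as.data.frame(series$truth$curves),
                  file.path(dir, "truth_curves.csv"))
  invisible(dir)
}

#' @rdname write_conductivity_series
#' @export
read_conductivity_series <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "series.yaml"))
  n <- meta$grid_n
  config <- config_from_list(meta$config)
  phantom <- build_phantom(n)
  times <- unlist(meta$times)
  fields <- array(NA_real_, c(n, n, length(times)))
  for (k in seq_along(times)) {
    df <- read_csv_strict(file.path(dir, sprintf("frame_%04d.csv", k)), expect_cols = n)
    fields[, , k] <- as.matrix(df)
  }
  curves <- as_tibble(read_csv_strict(file.path(dir, "truth_curves.csv")))
  structure(
    list(phantom = phantom, config = config, times = times, fields = fields,
         truth = list(curves = curves,
                      regions = scenario_regions(phantom, config)$table,
                      masks = scenario_regions(phantom, config)$masks)),
    class = "conductivity_series"
  )
}

#' Write a run manifest with file checksums
#'
#' Lists every regular file under `dir` (except the manifest itself) with
#' its MD5 checksum, plus the seed and package version. Re-running a
#' noiseless pipeline with the same configuration reproduces the
#' checksums.
#'
#' @param dir Run directory.
#' @param seed Seed recorded for the run.
#' @return Path of the manifest, invisibly.
#' @export
write_run_manifest <- function(dir, seed = NA_integer_) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.yaml"))
  sums <- tools::md5sum(file.path(dir, files))
  yaml::write_yaml(
    list(seed = seed,
         package_version = as.character(utils::packageVersion("eitperf")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         files = mapply(function(f, s) list(file = f, md5 = unname(s)),
                        files, sums, SIMPLIFY = FALSE, USE.NAMES = FALSE)),
    file.path(dir, "manifest.yaml")
  )
  invisible(file.path(dir, "manifest.yaml"))
}
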