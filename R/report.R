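# Markdown run report: curves per lung, functional images, metrics table,
# defect summary — one page per completed run directory.

#' Summarize a completed run directory as Markdown
#'
#' Collates the artifacts a pipeline run wrote under `rundir` (scenario
#' configuration, dilution curves and metrics, functional image renders,
#' defect fractions) into `report.md`. Stages that were not run are listed
#' as missing; perfusion sections of a ventilation-only run are marked not
#' applicable. Regeneration is deterministic for a fixed run directory.
#'
#' @param rundir Run directory produced by the pipeline CLI or by
#'   [run_scenario()] + the writers.
#' @return Path of `report.md`, invisibly.
#' @export
report <- function(rundir) {
  if (!dir.exists(rundir)) eit_abort(sprintf("No run directory: %s", rundir), "parameter")
  p <- function(...) file.path(rundir, ...)
  lines <- c("# EIT lung-perfusion run report", "")

  cfg <- NULL
  if (file.exists(p("config.yaml"))) {
    cfg <- read_scenario_config(p("config.yaml"))
    lines <- c(lines,
               sprintf("Scenario: **%s** (catheter %s, seed %d, noise_sd %g)",
                       cfg$scenario, cfg$catheter_side, cfg$seed, cfg$noise_sd), "")
    if (cfg$scenario != "ventilation_only") {
      lines <- c(lines,
                 sprintf("Bolus: %g ml, conductivity gain %g; flow split R/L = %g/%g; occluded fraction %g",
                         cfg$bolus_volume_ml, cfg$bolus_conductivity_gain,
                         cfg$flow_split[["right"]], cfg$flow_split[["left"]],
                         cfg$occluded_fraction), "")
    }
  }

  missing_stages <- character(0)
  is_vent <- !is.null(cfg) && cfg$scenario == "ventilation_only"

  lines <- c(lines, "## Functional images", "")
  for (img in c("ventilation", "perfusion")) {
    csv <- p(paste0(img, ".csv"))
    if (file.exists(csv)) {
      lines <- c(lines, sprintf("- %s image: `%s.csv`%s", img, img,
                                if (file.exists(p(paste0(img, ".png"))))
                                  sprintf(" (render `%s.png`)", img) else ""))
    } else if (img == "perfusion" && is_vent) {
      lines <- c(lines, "- perfusion image: not applicable (ventilation-only run)")
    } else if (img == "ventilation" && !is.null(cfg) && !is_vent) {
      lines <- c(lines, "- ventilation image: not applicable (breath-hold bolus run)")
    } else {
      missing_stages <- c(missing_stages, paste0(img, ".csv"))
    }
  }
  lines <- c(lines, "")

  lines <- c(lines, "## Dilution curves and metrics", "")
  if (is_vent) {
    lines <- c(lines, "Not applicable (ventilation-only run).", "")
  } else if (file.exists(p("curve_metrics.csv"))) {
    met <- read_csv_strict(p("curve_metrics.csv"))
    lines <- c(lines, paste("|", paste(names(met), collapse = " | "), "|"),
               paste("|", paste(rep("---", ncol(met)), collapse = " | "), "|"))
    for (i in seq_len(nrow(met))) {
      vals <- vapply(met[i, ], function(v) {
        if (is.numeric(v)) formatC(v, format = "g", digits = 4) else as.character(v)
      }, "")
      lines <- c(lines, paste("|", paste(vals, collapse = " | "), "|"))
    }
    lines <- c(lines, "")
    if (file.exists(p("curves.csv"))) {
      lines <- c(lines, "Curves: `curves.csv` (one row per location per frame).", "")
    }
  } else {
    missing_stages <- c(missing_stages, "curve_metrics.csv")
  }

  if (file.exists(p("flows.csv"))) {
    fl <- read_csv_strict(p("flows.csv"))
    lines <- c(lines, "## Relative regional flow (Stewart-Hamilton, 1/AUC)", "")
    for (i in seq_len(nrow(fl))) {
      lines <- c(lines, sprintf("- %s: %.3f", fl$region[i], fl$relative_flow[i]))
    }
    lines <- c(lines, "")
  }
  if (file.exists(p("defects.csv"))) {
    dd <- read_csv_strict(p("defects.csv"))
    lines <- c(lines, "## Perfusion defects", "")
    for (i in seq_len(nrow(dd))) {
      lines <- c(lines, sprintf("- %s lung: defect fraction %.3f", dd$lung[i],
                                dd$defect_fraction[i]))
    }
    lines <- c(lines, "")
  }

  if (length(missing_stages)) {
    lines <- c(lines, "## Missing artifacts", "",
               paste0("- `", missing_stages, "`"), "")
  }
  writeLines(lines, p("report.md"))
  invisible(p("report.md"))
}
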