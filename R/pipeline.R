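#' End-to-end pipeline
#'
#' Orchestrates generate -> classify -> LMI -> combinations -> uncertainty
#' -> report as one configured, seeded, logged run. Every stage output is a
#' pure function of the configuration and inputs, so a rerun with the same
#' configuration reproduces the CSV reports byte for byte.
#'
#' @name pipeline_cli
NULL

#' Run configuration
#'
#' @param scenario a [scenario_config()] (synthetic run) or `NULL` when
#'   `input_dir` points at an existing scenario directory.
#' @param input_dir optional directory of GeoTIFF inputs with a
#'   `manifest.json` (see [write_scenario()]).
#' @param strata which land-use strata to process.
#' @param uncertainty run the Monte-Carlo + RF stage.
#' @param n_sims,sd_fraction,n_trees,reps,sample_cap uncertainty settings;
#'   defaults are desk-scale (reference values: 20,000 draws, 1000 trees,
#'   20 repetitions).
#' @param seed global seed; stage seeds derive from it.
#' @export
run_config <- function(scenario = scenario_config(), input_dir = NULL,
                       strata = c("agricultural", "arable"),
                       uncertainty = TRUE, n_sims = 2000,
                       sd_fraction = 0.1, n_trees = 200, reps = 5,
                       sample_cap = 1e5, seed = 42) {
  strata <- match.arg(strata, several.ok = TRUE)
  structure(list(scenario = scenario, input_dir = input_dir,
                 strata = strata, uncertainty = uncertainty,
                 n_sims = n_sims, sd_fraction = sd_fraction,
                 n_trees = n_trees, reps = reps, sample_cap = sample_cap,
                 seed = seed),
            class = "lmdi_run_config")
}

#' Execute the full pipeline into a run directory
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results: `stack`,
#'   and per-stratum `lmi`, `classes`, `report`, `combos`, `uncertainty`,
#'   `ranges`; files written: critical masks, LMI and class grids
#'   (GeoTIFF), `zonal_report_<stratum>.csv`, `combos_<stratum>.csv`,
#'   `uncertainty_<stratum>.csv`, `importance_<stratum>.csv`,
#'   `run_manifest.json`.
#' @export
run_pipeline <- function(config, outdir, quiet = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %-12s %6.2f s", name, proc.time()[["elapsed"]] - t0)
    res
  }
  registry <- default_registry()

  world <- stage("inputs", {
    if (!is.null(config$input_dir)) read_scenario(config$input_dir)
    else {
      scn <- gen_process_inputs(config$scenario, registry)
      list(inputs = scn$inputs, land = scn$land, zones = scn$zones,
           truth = scn$truth)
    }
  })
  stack <- stage("classify", build_critical_stack(world$inputs, registry))
  for (pid in names(stack$masks))
    write_raster(stack$masks[[pid]],
                 file.path(outdir, paste0("critical_", pid, ".tif")),
                 "INT1U")

  out <- list(stack = stack, world = world)
  for (stratum in config$strata) {
    lmi <- stage(paste0("lmi_", stratum),
                 compute_lmi(stack$masks, world$land, stratum))
    classes <- classify_lmi(lmi)
    write_raster(lmi$counts,
                 file.path(outdir, paste0("lmi_", stratum, ".tif")),
                 "INT1U")
    write_raster(classes,
                 file.path(outdir, paste0("lmi_class_", stratum, ".tif")),
                 "INT1U")
    report <- stage(paste0("report_", stratum),
                    zonal_stats(classes, lmi, world$zones, world$land,
                                stratum = stratum))
    utils::write.csv(report,
                     file.path(outdir,
                               paste0("zonal_report_", stratum, ".csv")),
                     row.names = FALSE)
    combos <- stage(paste0("combos_", stratum),
                    enumerate_combos(stack$masks, classes))
    utils::write.csv(combos,
                     file.path(outdir, paste0("combos_", stratum, ".csv")),
                     row.names = FALSE)
    res <- list(lmi = lmi, classes = classes, report = report,
                combos = combos)
    if (config$uncertainty) {
      unc <- stage(paste0("uncertainty_", stratum), {
        im <- build_input_matrix(stack, lmi, sample_n = config$sample_cap,
                                 seed = config$seed + 1)
        samples <- sample_thresholds(registry, config$n_sims,
                                     config$sd_fraction,
                                     seed = config$seed + 2)
        sim <- simulate_lmi_labels(im, samples, registry)
        rf <- fit_rf_uncertainty(im, samples, registry,
                                 n_trees = config$n_trees,
                                 reps = config$reps,
                                 seed = config$seed + 3)
        ranges <- class_area_error_ranges(rf, sim,
                                          cell_size_m = classes$cell_size)
        list(im = im, sim = sim, rf = rf, ranges = ranges)
      })
      utils::write.csv(unc$ranges,
                       file.path(outdir,
                                 paste0("uncertainty_", stratum, ".csv")),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(column = names(unc$rf$importance),
                   importance = as.numeric(unc$rf$importance),
                   oob_error = unc$rf$oob_error),
        file.path(outdir, paste0("importance_", stratum, ".csv")),
        row.names = FALSE)
      res$uncertainty <- unc$rf
      res$ranges <- unc$ranges
    }
    out[[stratum]] <- res
  }
  jsonlite::write_json(
    list(seed = config$seed, strata = config$strata,
         n_sims = if (config$uncertainty) config$n_sims else 0,
         sd_fraction = config$sd_fraction,
         n_trees = config$n_trees, reps = config$reps,
         missing_processes = stack$missing,
         package_version = as.character(utils::packageVersion("lmdi"))),
    file.path(outdir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(out)
}

#' Command-line entry point
#'
#' Invoked by `inst/cli/lmdi_run.R`; parses `--seed`, `--outdir`,
#' `--stratum`, `--n-sims`, `--quick` and dispatches [run_pipeline()] on a
#' synthetic scenario (or `--input-dir` on prepared rasters).
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @export
lmdi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    hit <- which(args == flag)
    if (length(hit)) args[hit[1] + 1] else default
  }
  seed <- as.integer(get_opt("--seed", "42"))
  outdir <- get_opt("--outdir", "lmdi_run")
  stratum <- get_opt("--stratum", "both")
  strata <- if (stratum == "both") c("agricultural", "arable") else stratum
  quick <- "--quick" %in% args
  cfg <- run_config(
    scenario = scenario_config(seed = seed,
                               shape = if (quick) c(48, 48) else c(64, 64)),
    input_dir = get_opt("--input-dir"),
    strata = strata,
    uncertainty = !("--no-uncertainty" %in% args),
    n_sims = as.integer(get_opt("--n-sims", if (quick) "500" else "2000")),
    n_trees = if (quick) 100 else 200,
    reps = if (quick) 3 else 5,
    seed = seed)
  run_pipeline(cfg, outdir, quiet = FALSE)
  invisible(0L)
}
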