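# Orchestration: simulate -> fit -> correlate -> report, runnable from R or
# from the thin command-line script shipped in inst/scripts/eisgrowth.
# Every stage is deterministic under a fixed seed, validates its
# configuration before touching the filesystem, and logs its inputs (config
# digest, file checksums) to stderr.

.pipeline_keys <- c("preset", "times", "n_reactors", "conditions",
                    "seed", "out_dir",
                    "grid_n", "grid_f_min", "grid_f_max",
                    "noise_sigma_rel", "noise_sigma_abs",
                    "growth_jitter_sd", "series_resistance",
                    "weighting", "max_iterations", "fix_d0_zero",
                    "free_exponents",
                    "window_mode", "window", "window_frac", "match_tol_h",
                    "correlate_condition")

#' Pipeline configuration
#'
#' Assembles and validates the settings of the end-to-end pipeline. Unknown
#' keys are rejected by name, so a misspelled setting fails immediately
#' instead of silently using a default. `as_pipeline_config()` performs the
#' same validation on a plain list, e.g. one loaded from a YAML file.
#'
#' @param preset Synthetic preset (see [experiment_config()]).
#' @param times Sampling times (h).
#' @param n_reactors Replicates per condition.
#' @param conditions Conditions to simulate.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param grid_n,grid_f_min,grid_f_max Frequency grid settings.
#' @param noise_sigma_rel,noise_sigma_abs Reactance noise.
#' @param growth_jitter_sd Replicate spread of the initial CFU count.
#' @param series_resistance Real-channel stub (ohm).
#' @param weighting,max_iterations,fix_d0_zero,free_exponents Fit settings
#'   (see [fit_config()]); `free_exponents = TRUE` runs the free-exponent
#'   stage per reactor instead of the fixed stage when fitting.
#' @param window_mode,window,window_frac,match_tol_h Correlation settings
#'   (see [exponential_window()] and [correlate_supercap_cfu()]).
#' @param correlate_condition Condition whose summary is correlated
#'   (default both, one result per condition present).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "kpneumoniae_like", times = 1:10,
                            n_reactors = 3,
                            conditions = c("with_pb", "without_pb"),
                            seed = 1L, out_dir = "eisgrowth-run",
                            grid_n = 61, grid_f_min = 10, grid_f_max = 1e6,
                            noise_sigma_rel = 0.01, noise_sigma_abs = 0,
                            growth_jitter_sd = 0.05, series_resistance = 50,
                            weighting = "none", max_iterations = 50000,
                            fix_d0_zero = FALSE, free_exponents = FALSE,
                            window_mode = "manual", window = c(0, 6),
                            window_frac = 0.5, match_tol_h = 0.5,
                            correlate_condition = NULL) {
  cfg <- list(preset = preset, times = times, n_reactors = n_reactors,
              conditions = conditions, seed = seed, out_dir = out_dir,
              grid_n = grid_n, grid_f_min = grid_f_min,
              grid_f_max = grid_f_max,
              noise_sigma_rel = noise_sigma_rel,
              noise_sigma_abs = noise_sigma_abs,
              growth_jitter_sd = growth_jitter_sd,
              series_resistance = series_resistance,
              weighting = weighting, max_iterations = max_iterations,
              fix_d0_zero = fix_d0_zero, free_exponents = free_exponents,
              window_mode = window_mode, window = window,
              window_frac = window_frac, match_tol_h = match_tol_h,
              correlate_condition = correlate_condition)
  as_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param x A named list of settings (e.g. from [read_pipeline_config()]).
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), .pipeline_keys)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  defaults <- formals(pipeline_config)
  for (k in setdiff(.pipeline_keys, names(x))) {
    v <- defaults[[k]]
    x[[k]] <- if (is.language(v)) eval(v) else v
  }
  stopifnot(x$preset %in% c("kpneumoniae_like", "pbifermentans_like"),
            all(x$conditions %in% c("with_pb", "without_pb")),
            x$window_mode %in% c("manual", "auto"),
            length(x$window) == 2)
  x$seed <- as.integer(x$seed)
  structure(x, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with pipeline settings; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  as_pipeline_config(yaml::read_yaml(path))
}

pipeline_log <- function(...) {
  message(sprintf("[eisgrowth %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}

config_digest <- function(cfg) {
  # order-independent short digest of the config for the run log
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

file_checksum <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", file.info(path)$size)
  sprintf("%08x", sum(as.integer(bytes) *
                        (seq_along(bytes) %% 251 + 1)) %% .Machine$integer.max)
}

experiment_from_pipeline <- function(cfg) {
  experiment_config(preset = cfg$preset, times = cfg$times,
                    n_reactors = cfg$n_reactors,
                    conditions = cfg$conditions,
                    grid = default_grid(cfg$grid_n, cfg$grid_f_min,
                                        cfg$grid_f_max),
                    noise_sigma_rel = cfg$noise_sigma_rel,
                    noise_sigma_abs = cfg$noise_sigma_abs,
                    growth_jitter_sd = cfg$growth_jitter_sd,
                    series_resistance = cfg$series_resistance,
                    seed = cfg$seed)
}

fit_config_from_pipeline <- function(cfg) {
  fit_config(weighting = cfg$weighting,
             max_iterations = cfg$max_iterations,
             fix_d0_zero = cfg$fix_d0_zero)
}

#' Pipeline stage: simulate a synthetic dataset
#'
#' Writes `spectra.csv`, `growth.csv`, `pb.csv` and `truth.json` under the
#' configured output directory.
#'
#' @param config A `pipeline_config` (or a list coercible to one).
#' @return Invisibly, the list of file paths.
#' @export
pipeline_simulate <- function(config) {
  cfg <- as_pipeline_config(config)
  pipeline_log("simulate: preset %s, seed %d, config %s",
               cfg$preset, cfg$seed, config_digest(cfg))
  res <- simulate_experiment(experiment_from_pipeline(cfg), cfg$out_dir)
  for (p in res$paths)
    pipeline_log("wrote %s (checksum %s)", p, file_checksum(p))
  invisible(res$paths)
}

#' Pipeline stage: fit every sweep and summarise replicates
#'
#' Reads a spectra CSV, fits every (condition, reactor, time) sweep, and
#' writes `fits.csv` (one row per reactor and time) and `summary.csv` (one
#' replicate-averaged row per condition and time).
#'
#' @param spectra_csv Path to a long-format spectra CSV.
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the `summary` and `fits` data.frames and
#'   their file paths.
#' @export
pipeline_fit <- function(spectra_csv = NULL, config) {
  cfg <- as_pipeline_config(config)
  if (is.null(spectra_csv)) spectra_csv <- file.path(cfg$out_dir, "spectra.csv")
  if (!file.exists(spectra_csv)) stop("spectra file not found: ", spectra_csv)
  pipeline_log("fit: %s (checksum %s), config %s", spectra_csv,
               file_checksum(spectra_csv), config_digest(cfg))
  spectra <- read_spectra(spectra_csv)
  if (length(spectra) == 0) stop("no spectra parsed from ", spectra_csv)
  fcfg <- fit_config_from_pipeline(cfg)
  summary <- fit_timecourse(spectra, fcfg)
  fits <- attr(summary, "fits")
  if (isTRUE(cfg$free_exponents)) {
    free <- lapply(spectra, fit_free_exponents, config = fcfg)
    fits$p1_free <- vapply(free, function(f) f$params$p1, 0)[
      order(vapply(spectra, `[[`, "", "condition"),
            vapply(spectra, `[[`, "", "reactor_id"),
            vapply(spectra, `[[`, 0, "time_h"))]
    fits$p2_free <- vapply(free, function(f) f$params$p2, 0)[
      order(vapply(spectra, `[[`, "", "condition"),
            vapply(spectra, `[[`, "", "reactor_id"),
            vapply(spectra, `[[`, 0, "time_h"))]
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fits = file.path(cfg$out_dir, "fits.csv"),
                summary = file.path(cfg$out_dir, "summary.csv"))
  utils::write.csv(fits, paths$fits, row.names = FALSE)
  utils::write.csv(summary, paths$summary, row.names = FALSE)
  pipeline_log("wrote %s, %s", paths$fits, paths$summary)
  invisible(list(summary = summary, fits = fits, paths = paths))
}

#' Pipeline stage: correlate supercapacitance with CFU counts
#'
#' Reads the replicate summary and growth tables, restricts to the
#' exponential window, regresses the replicate-mean `-b0` on the CFU count
#' per condition, and writes `correlation.json` plus a short Markdown
#' report.
#'
#' @param summary_csv,growth_csv Paths (defaults under the configured
#'   output directory).
#' @param config A `pipeline_config`.
#' @return Invisibly, the list of per-condition `supercap_correlation`
#'   results.
#' @export
pipeline_correlate <- function(summary_csv = NULL, growth_csv = NULL,
                               config) {
  cfg <- as_pipeline_config(config)
  if (is.null(summary_csv)) summary_csv <- file.path(cfg$out_dir, "summary.csv")
  if (is.null(growth_csv)) growth_csv <- file.path(cfg$out_dir, "growth.csv")
  for (p in c(summary_csv, growth_csv))
    if (!file.exists(p)) stop("input not found: ", p)
  pipeline_log("correlate: %s (%s), %s (%s), config %s",
               summary_csv, file_checksum(summary_csv),
               growth_csv, file_checksum(growth_csv), config_digest(cfg))
  summary <- utils::read.csv(summary_csv, stringsAsFactors = FALSE)
  growth <- read_growth(growth_csv)
  conds <- cfg$correlate_condition
  if (is.null(conds)) conds <- unique(summary$condition)

  results <- list()
  for (cond in conds) {
    st <- summary[summary$condition == cond, , drop = FALSE]
    gl <- Filter(function(g) g$condition[1] == cond, growth)
    if (nrow(st) == 0 || length(gl) == 0)
      stop("no data for condition ", cond)
    gmean <- mean_growth(gl)
    window <- if (cfg$window_mode == "manual") cfg$window
              else exponential_window(gmean, "auto", frac = cfg$window_frac)
    results[[cond]] <- correlate_supercap_cfu(st, gmean, window,
                                              cfg$match_tol_h)
  }

  json <- lapply(results, function(r)
    list(slope = r$slope, intercept = r$intercept, r_squared = r$r_squared,
         n = r$n, window = r$window))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(cfg$out_dir, "correlation.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  report <- c("# Supercapacitance vs CFU correlation", "",
              sprintf("Fitted quantity: replicate-mean -b0 against log10(CFU/mL), window as configured (%s).",
                      cfg$window_mode))
  for (cond in names(results)) {
    r <- results[[cond]]
    report <- c(report, "",
                sprintf("## %s", cond),
                sprintf("- window: %g to %g h", r$window[1], r$window[2]),
                sprintf("- n matched points: %d", r$n),
                sprintf("- slope: %.6g per log10 CFU/mL", r$slope),
                sprintf("- intercept: %.6g", r$intercept),
                sprintf("- R^2: %.4f", r$r_squared))
  }
  report_path <- file.path(cfg$out_dir, "report.md")
  writeLines(report, report_path)
  pipeline_log("wrote %s, %s", json_path, report_path)
  invisible(results)
}

#' Run the full pipeline
#'
#' simulate -> fit -> correlate under one configuration and seed;
#' deterministic and idempotent (re-running with the same config rewrites
#' identical outputs).
#'
#' @param config A `pipeline_config` (or list / YAML-loaded settings).
#' @return Invisibly, the correlation results.
#' @export
pipeline_run_all <- function(config) {
  cfg <- as_pipeline_config(config)
  pipeline_simulate(cfg)
  pipeline_fit(config = cfg)
  pipeline_correlate(config = cfg)
}
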