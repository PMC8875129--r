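# Pipeline orchestration: a single validated configuration object drives
# simulation, analysis and QC runs, and every applied default is logged.

.config_defaults <- list(
  wells = NULL, standards = NULL, resistance = NULL, qc = NULL,
  out_dir = "results",
  window = NULL, er_threshold = 1.5, teer_threshold = 300,
  split_at = NULL, weighting = "none",
  alpha = 0.05, p_adjust = "none", contrasts = NULL,
  simulation = NULL, seed = 1L)

#' Build a run configuration
#'
#' Collects every pipeline option with its default; unspecified options are
#' recorded so a run can log exactly which defaults were applied. The
#' object round-trips losslessly through [write_run_config()] /
#' [read_run_config()] (YAML).
#'
#' @param ... any of: `wells`, `standards`, `resistance`, `qc` (input CSV
#'   paths); `out_dir`; `window` (minutes, `c(lo, hi)`); `er_threshold`;
#'   `teer_threshold`; `split_at`; `weighting`; `alpha`; `p_adjust`;
#'   `contrasts` (list of `c(baseline, treated)`); `simulation` (list: the
#'   [transport_sim_params()] fields plus `times`, `vs` and a `conditions`
#'   list, each condition a list with `label`, `c0`, `n_wells` and optional
#'   parameter overrides such as `inhibition`); `seed`.
#' @return list of class `run_config`, with attribute `defaults_applied`.
#' @export
run_config <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), names(.config_defaults))
  if (length(unknown))
    validation_error(paste0("unknown config option(s): ",
                            paste(unknown, collapse = ", ")))
  cfg <- .config_defaults
  cfg[names(user)] <- user
  structure(cfg, class = "run_config",
            defaults_applied = setdiff(names(.config_defaults), names(user)))
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) schema_error("config file not found", file = path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  # only options the user set are written, so a re-read reconstructs both
  # the values and which options were defaulted
  set_opts <- setdiff(names(.config_defaults),
                      attr(config, "defaults_applied"))
  keep <- config[set_opts]
  yaml::write_yaml(keep[!vapply(keep, is.null, logical(1))], path)
  invisible(path)
}

.write_log <- function(config, out_dir, extra = character()) {
  applied <- attr(config, "defaults_applied")
  set_opts <- setdiff(names(.config_defaults), applied)
  lines <- c(
    paste0("defaults applied: ",
           if (length(applied)) paste(applied, collapse = ", ") else "none"),
    paste0("options set: ",
           if (length(set_opts)) paste(set_opts, collapse = ", ") else "none"),
    extra)
  writeLines(lines, file.path(out_dir, "run_log.txt"))
}

.sim_params_from_config <- function(sim, overrides = list()) {
  fields <- c("p_passive", "vmax", "km", "inhibition", "area", "vol_ap",
              "vol_bl", "noise_cv", "seed")
  args <- sim[intersect(names(sim), fields)]
  args[names(overrides)] <- overrides
  do.call(transport_sim_params, args)
}

#' Simulate a dataset from a configuration
#'
#' Runs the mechanistic simulator for every condition in the configuration
#' `simulation` block and writes `wells.csv`, a `truth.csv` sidecar (with
#' matching well ids) and a `manifest.yaml` recording the seed and
#' parameters. When the block has a `standards` sub-list (with `slope`,
#' `intercept`, optional `noise_cv`), a `standards.csv` is written too.
#'
#' @param config a [run_config()] with a non-`NULL` `simulation` block.
#' @return invisibly, a list with the written file paths and the combined
#'   `simulated_dataset` tables.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$simulation
  if (is.null(sim)) validation_error("config has no 'simulation' block")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- sampling_schedule(
    times = if (is.null(sim$times)) c(30, 60, 90, 120, 150, 180)
            else unlist(sim$times),
    vs = if (is.null(sim$vs)) 0.2 else sim$vs)
  conds <- sim$conditions
  if (is.null(conds))
    conds <- list(list(label = "cond", c0 = 100, n_wells = 3))
  master_seed <- as.integer(config$seed)
  all_wells <- list(); all_truth <- list()
  for (i in seq_along(conds)) {
    cd <- conds[[i]]
    overrides <- cd[intersect(names(cd), c("p_passive", "vmax", "km",
                                           "inhibition", "noise_cv"))]
    params <- .sim_params_from_config(sim, overrides)
    ds <- simulate_condition(
      params, schedule, c0_list = unlist(cd$c0),
      n_wells = if (is.null(cd$n_wells)) 3L else cd$n_wells,
      seed = master_seed + 1000L * i,
      directions = if (is.null(cd$directions)) DIRECTIONS
                   else unlist(cd$directions),
      condition = if (is.null(cd$label)) paste0("cond", i) else cd$label,
      compound = if (is.null(cd$compound)) "drug" else cd$compound)
    # prefix well ids with the condition index so they stay unique
    ds$wells$well_id <- paste0("C", i, "_", ds$wells$well_id)
    ds$truth$well_id <- paste0("C", i, "_", ds$truth$well_id)
    all_wells[[i]] <- ds$wells; all_truth[[i]] <- ds$truth
  }
  wells <- do.call(rbind, all_wells)
  truth <- do.call(rbind, all_truth)
  paths <- list(wells = file.path(out_dir, "wells.csv"),
                truth = file.path(out_dir, "truth.csv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  write_wells(wells, paths$wells)
  utils::write.csv(truth, paths$truth, row.names = FALSE, quote = FALSE)
  if (!is.null(sim$standards)) {
    st <- sim$standards
    std <- generate_standards(
      nominal_concs = if (is.null(st$nominal_concs))
        eval(formals(generate_standards)$nominal_concs) else
          unlist(st$nominal_concs),
      slope = st$slope, intercept = st$intercept,
      noise_cv = if (is.null(st$noise_cv)) 0 else st$noise_cv,
      seed = master_seed,
      analyte = if (is.null(st$analyte)) "analyte" else st$analyte)
    names(std)[names(std) == "nominal_conc"] <- "nominal_conc_ug_per_ml"
    paths$standards <- file.path(out_dir, "standards.csv")
    utils::write.csv(std, paths$standards, row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(list(seed = master_seed,
                        simulation = sim,
                        files = lapply(paths, basename)),
                   paths$manifest)
  .write_log(config, out_dir, sprintf("simulated %d wells under seed %d",
                                      length(unique(wells$well_id)),
                                      master_seed))
  invisible(list(paths = paths, wells = wells, truth = truth))
}

#' Analyse a dataset from a configuration
#'
#' End-to-end analysis run: reads the wells table (and, when configured,
#' calibration standards and resistance records), computes per-well
#' dilution-corrected transport and Papp, per-condition summaries with
#' efflux ratios and mechanism classification, optional pairwise effect
#' contrasts, and writes `well_results.csv`, `group_summary.csv`,
#' `report.txt`, plus `teer_report.csv` / `calibration_report.csv` /
#' `effects.csv` when the corresponding inputs are configured.
#'
#' @param config a [run_config()] whose `wells` points at a CSV (or is a
#'   data.frame).
#' @return invisibly, a list with `well_results`, `summaries`, `effects`,
#'   `teer`, `calibration`, and the written `paths`.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$wells)) validation_error("config has no 'wells' input")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wells <- if (is.data.frame(config$wells)) validate_wells(config$wells)
           else read_wells(config$wells)
  paths <- list()

  calib <- NULL
  if (!is.null(config$standards)) {
    std <- if (is.data.frame(config$standards)) config$standards
           else read_standards(config$standards)
    calib <- lapply(split(std, std$analyte), fit_calibration,
                    split_at = config$split_at,
                    weighting = config$weighting)
    seg <- do.call(rbind, lapply(calib, function(cv)
      cbind(analyte = cv$analyte, cv$segments, lloq = cv$lloq)))
    paths$calibration <- file.path(out_dir, "calibration_report.csv")
    utils::write.csv(seg, paths$calibration, row.names = FALSE, quote = FALSE)
  }

  teer_rep <- NULL
  if (!is.null(config$resistance)) {
    res <- if (is.data.frame(config$resistance)) config$resistance
           else read_resistance(config$resistance)
    teer_rep <- assess_teer(res, threshold = config$teer_threshold)
    paths$teer <- file.path(out_dir, "teer_report.csv")
    utils::write.csv(teer_rep, paths$teer, row.names = FALSE, quote = FALSE)
  }

  well_results <- analyze_wells(wells, window = config$window)
  summaries <- summarize_groups(well_results,
                                er_threshold = config$er_threshold)
  effects <- NULL
  if (!is.null(config$contrasts))
    effects <- effect_table(well_results, config$contrasts,
                            alpha = config$alpha,
                            p_adjust = config$p_adjust)
  report <- build_report(summaries, effects)
  paths$well_results <- file.path(out_dir, "well_results.csv")
  paths$group_summary <- file.path(out_dir, "group_summary.csv")
  paths$report <- file.path(out_dir, "report.txt")
  utils::write.csv(well_results, paths$well_results, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(summaries, paths$group_summary, row.names = FALSE,
                   quote = FALSE)
  writeLines(report$text, paths$report)
  if (!is.null(effects)) {
    paths$effects <- file.path(out_dir, "effects.csv")
    utils::write.csv(effects, paths$effects, row.names = FALSE, quote = FALSE)
  }
  .write_log(config, out_dir,
             sprintf("analysed %d wells in %d condition(s)",
                     nrow(well_results), nrow(summaries)))
  invisible(list(well_results = well_results, summaries = summaries,
                 effects = effects, teer = teer_rep, calibration = calib,
                 paths = paths))
}

#' Run precision/recovery QC from a configuration
#'
#' Reads a QC CSV (`analyte, nominal_conc_ug_per_ml, measured_conc_ug_per_ml`,
#' optional `day`) and writes per-analyte precision and recovery statistics.
#'
#' @param config a [run_config()] whose `qc` points at a CSV (or is a
#'   data.frame).
#' @return invisibly, the per-analyte QC report data.frame.
#' @export
run_qc <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$qc)) validation_error("config has no 'qc' input")
  df <- if (is.data.frame(config$qc)) config$qc else .read_csv(config$qc, "QC")
  .require_columns(df, c("analyte", "nominal_conc_ug_per_ml",
                         "measured_conc_ug_per_ml"),
                   if (is.character(config$qc)) config$qc else NULL, "QC")
  names(df)[names(df) == "nominal_conc_ug_per_ml"] <- "nominal"
  names(df)[names(df) == "measured_conc_ug_per_ml"] <- "measured"
  rep_ <- do.call(rbind, lapply(split(df, df$analyte), function(g)
    cbind(analyte = g$analyte[1], qc_stats(g))))
  rownames(rep_) <- NULL
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep_, file.path(config$out_dir, "qc_report.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(rep_)
}
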