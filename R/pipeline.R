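#' Resolve and validate a pipeline run configuration
#'
#' The whole analysis is driven by one structured configuration, supplied
#' either as a named list or as the path to a YAML file. Unknown fields are
#' rejected; the resolved configuration (defaults filled in) is serialized
#' into every run's output directory so a run can be re-executed
#' bit-identically.
#'
#' Fields: `down_csv`/`up_csv` (paths to weekly CSVs) or `synth` (a list of
#' [synth_config()] overrides — used when no paths are given); `variant`
#' (`"ELM1"` or `"ELM2"`); `split_mode` and `split_seed`; `L_range`;
#' `activation`; `elm_seeds` (hidden-layer seeds averaged in reports);
#' `sweep_seeds` (seeds per sweep candidate); `baselines` (subset of
#' `"LR"`, `"NN-BP"`, `"ANFIS"`); `nn_learning_rate`, `nn_epochs`,
#' `anfis_r`; `out_dir`.
#'
#' @param config named list or YAML file path.
#' @return validated `"run_config"` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    down_csv = NULL, up_csv = NULL, synth = list(),
    variant = "ELM2", split_mode = "chronological", split_seed = 1L,
    L_range = 2:30, activation = "sigmoid",
    elm_seeds = 1:30, sweep_seeds = 1:10,
    baselines = c("LR", "NN-BP", "ANFIS"),
    nn_learning_rate = 0.001, nn_epochs = 1000L, anfis_r = c(2L, 3L),
    out_dir = "elmbloom_run"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("run_config(): unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  cfg$variant <- match.arg(cfg$variant, c("ELM1", "ELM2", "custom"))
  cfg$split_mode <- match.arg(cfg$split_mode, c("chronological", "random"))
  cfg$activation <- match.arg(cfg$activation, c("sigmoid", "rbf", "sine"))
  if (cfg$variant == "ELM2" && !is.null(cfg$down_csv) && is.null(cfg$up_csv))
    stop("run_config(): variant ELM2 with file input requires 'up_csv'",
         call. = FALSE)
  cfg$L_range <- as.integer(cfg$L_range)
  structure(cfg, class = "run_config")
}

write_run_provenance <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dump <- unclass(cfg)
  dump$L_range <- as.integer(dump$L_range)
  dump$resolved_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dump$r_version <- as.character(getRversion())
  yaml::write_yaml(dump, file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

load_pair_inputs <- function(cfg) {
  if (!is.null(cfg$down_csv)) {
    down <- read_weekly_csv(cfg$down_csv)
    up <- if (!is.null(cfg$up_csv)) read_weekly_csv(cfg$up_csv) else NULL
    list(down = down, up = up, truth = NULL)
  } else {
    pair <- generate_pair(do.call(synth_config, cfg$synth))
    list(down = pair$down, up = pair$up, truth = pair$truth)
  }
}

#' Simulate a weir pair and write the weekly CSVs
#'
#' Wraps [generate_pair()]: writes `upstream.csv`, `downstream.csv` and the
#' noise-free `truth.csv` sidecar into the output directory, together with
#' the resolved configuration.
#'
#' @param config a `"run_config"`, list, or YAML path.
#' @return (invisibly) named vector of written file paths.
#' @export
cmd_simulate <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  pair <- generate_pair(do.call(synth_config, cfg$synth))
  write_run_provenance(cfg, cfg$out_dir)
  paths <- c(up = file.path(cfg$out_dir, "upstream.csv"),
             down = file.path(cfg$out_dir, "downstream.csv"),
             truth = file.path(cfg$out_dir, "truth.csv"))
  write_weekly_csv(pair$up, paths["up"])
  write_weekly_csv(pair$down, paths["down"])
  write_truth_csv(pair$truth, paths["truth"])
  invisible(paths)
}

#' Fit the chlorophyll-a ELM end to end
#'
#' Assembles the requested feature design, splits 50/50, sweeps the
#' hidden-node count, refits at the selected count and writes the fit
#' report, the sweep curve and the serialized model into the output
#' directory.
#'
#' @param config a `"run_config"`, list, or YAML path.
#' @return (invisibly) list with `report` (`"fit_report"`), `sweep`
#'   (`"node_sweep"`), `model` (`"elm"` at the first ELM seed), `split`.
#' @export
cmd_fit <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  inputs <- load_pair_inputs(cfg)
  set <- assemble_features(inputs$down, variant = cfg$variant, up = inputs$up)
  split <- split_half(set, mode = cfg$split_mode, seed = cfg$split_seed)
  sweep <- select_hidden_nodes(split$train, split$test, L_range = cfg$L_range,
                               activation = cfg$activation,
                               seeds = cfg$sweep_seeds)
  report <- evaluate_elm_seeds(split, L = sweep$selected_L,
                               activation = cfg$activation,
                               seeds = cfg$elm_seeds,
                               label = paste0("ELM (", cfg$variant, ")"))
  model <- elm(split$train, L = sweep$selected_L, activation = cfg$activation,
               seed = cfg$elm_seeds[1L])
  write_run_provenance(cfg, cfg$out_dir)
  utils::write.csv(as.data.frame(report),
                   file.path(cfg$out_dir, "fit_report.csv"), row.names = FALSE)
  utils::write.csv(sweep$table, file.path(cfg$out_dir, "node_sweep.csv"),
                   row.names = FALSE)
  elm_save(model, file.path(cfg$out_dir, "elm_model.json"))
  invisible(list(report = report, sweep = sweep, model = model,
                 split = split))
}

#' Run the full model comparison
#'
#' Fits the ELM1 and ELM2 feature designs plus the enabled baselines on one
#' shared split, writes the comparison grid and the feature-design
#' improvement table.
#'
#' @param config a `"run_config"`, list, or YAML path.
#' @return (invisibly) list with `comparison` (`"comparison_report"`),
#'   `improvement` (`"improvement_report"`), `elm1`, `elm2` fit reports.
#' @export
cmd_compare <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  inputs <- load_pair_inputs(cfg)
  if (is.null(inputs$up))
    stop("cmd_compare(): comparison needs both sites (ELM2 features)",
         call. = FALSE)
  set1 <- assemble_features(inputs$down, variant = "ELM1")
  set2 <- assemble_features(inputs$down, variant = "ELM2", up = inputs$up)
  split1 <- split_half(set1, mode = cfg$split_mode, seed = cfg$split_seed)
  split2 <- split_half(set2, mode = cfg$split_mode, seed = cfg$split_seed)

  sweep <- select_hidden_nodes(split2$train, split2$test,
                               L_range = cfg$L_range,
                               activation = cfg$activation,
                               seeds = cfg$sweep_seeds)
  elm1 <- evaluate_elm_seeds(split1, L = sweep$selected_L,
                             activation = cfg$activation,
                             seeds = cfg$elm_seeds, label = "ELM (ELM1)")
  comparison <- compare_models(split2, config = list(
    models = c("ELM", cfg$baselines),
    elm_L = sweep$selected_L, activation = cfg$activation,
    elm_seeds = cfg$elm_seeds,
    nn_learning_rate = cfg$nn_learning_rate, nn_epochs = cfg$nn_epochs,
    anfis_r = cfg$anfis_r))
  elm2 <- comparison$reports[["ELM (ELM2)"]]
  improvement <- improvement_percent(elm1, elm2)

  write_run_provenance(cfg, cfg$out_dir)
  write_comparison_csv(comparison, file.path(cfg$out_dir, "comparison.csv"))
  utils::write.csv(as.data.frame(improvement),
                   file.path(cfg$out_dir, "improvement.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep$table, file.path(cfg$out_dir, "node_sweep.csv"),
                   row.names = FALSE)
  invisible(list(comparison = comparison, improvement = improvement,
                 elm1 = elm1, elm2 = elm2, sweep = sweep))
}
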