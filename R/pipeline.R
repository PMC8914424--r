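# Config-driven pipeline tying the stages together and writing plain CSV /
# JSON artifacts plus a manifest, so a full analysis is reproducible from a
# single command. inst/cli/biledrain.R is a thin shell wrapper around
# run_pipeline().

PIPELINE_COMMANDS <- c("base-case", "psa", "sensitivity", "simulate",
                       "trial-compare", "full-run")

default_run_config <- function() {
  list(
    eus_events = 8L, eus_trials = 34L,
    ptbd_events = 17L, ptbd_trials = 32L,
    horizon_days = 30, discount_rate = 0,
    psa = list(n_trials = 10000L, ci_level = 0.95, beta_rule = "counts"),
    grid = list(p_min = 0, p_max = 0.5, step = 0.01),
    bootstrap = list(n_boot = 1000L, method = "bc", statistic = "mean"),
    seed = 20220225L
  )
}

# Recursively overlay user config onto defaults.
merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run an analysis pipeline command
#'
#' Executes one stage (or all of them) against the packaged fee schedules
#' and a configuration list, writing diff-able CSV/JSON artifacts under
#' `out_dir` together with a manifest that echoes the fully resolved
#' configuration, seed and package version, plus every modelling default the
#' run relied on (beta rule, bootstrap statistic, grid step). Inputs are
#' never mutated.
#'
#' Commands: `"base-case"`, `"psa"`, `"sensitivity"`, `"simulate"` (writes a
#' synthetic patient-records CSV), `"trial-compare"` (reads a records CSV,
#' or the simulated one under `full-run`), `"full-run"` (all of the above).
#'
#' @param command One of the commands above.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration: a named list or a path to a YAML
#'   file, overlaid onto the package defaults.
#' @param records_path Patient-records CSV for `"trial-compare"`; defaults to
#'   the file written by `"simulate"` in `out_dir`.
#' @param seed Overrides the config seed.
#' @param plots If `TRUE`, also write ggplot figures (PSA cost distributions,
#'   preference surface) as PNG.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(command = "full-run", out_dir = tempfile("biledrain-"),
                         config = NULL, records_path = NULL, seed = NULL,
                         plots = FALSE) {
  if (!command %in% PIPELINE_COMMANDS) {
    abort(sprintf("unknown command '%s'; expected one of: %s", command,
                  paste(PIPELINE_COMMANDS, collapse = ", ")))
  }
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  model <- decision_model(
    build_strategy_inputs(
      us_medicare_schedule(),
      reintervention_evidence(cfg$eus_events, cfg$eus_trials),
      reintervention_evidence(cfg$ptbd_events, cfg$ptbd_trials)
    ),
    horizon_days = cfg$horizon_days, discount_rate = cfg$discount_rate
  )

  if (command %in% c("base-case", "full-run")) {
    bc <- run_base_case(model)
    path <- file.path(out_dir, "base_case.json")
    write_json_report(list(
      costs = tidy(bc), savings = bc$savings,
      preferred = if (bc$tie) NULL else bc$preferred, tie = bc$tie,
      inputs = list(eus = unclass(model$strategies[[1]]$profile)[-1],
                    ptbd = unclass(model$strategies[[2]]$profile)[-1],
                    eus_counts = c(cfg$eus_events, cfg$eus_trials),
                    ptbd_counts = c(cfg$ptbd_events, cfg$ptbd_trials))
    ), path)
    emit(path)
    path <- file.path(out_dir, "base_case.csv")
    readr::write_csv(tidy(bc), path); emit(path)
  }

  if (command %in% c("psa", "full-run")) {
    psa <- run_psa(model, psa_settings(
      n_trials = cfg$psa$n_trials, seed = cfg$seed,
      ci_level = cfg$psa$ci_level, beta_rule = cfg$psa$beta_rule
    ))
    path <- file.path(out_dir, "psa_summary.json")
    write_json_report(list(
      settings = psa$settings, summary = tidy(psa),
      prob_cost_saving = psa$prob_cost_saving
    ), path)
    emit(path)
    path <- file.path(out_dir, "psa_samples.csv")
    readr::write_csv(psa$samples, path); emit(path)
    if (plots) {
      path <- file.path(out_dir, "psa_costs.png")
      ggplot2::ggsave(path, autoplot(psa), width = 7, height = 4, dpi = 150)
      emit(path)
    }
  }

  if (command %in% c("sensitivity", "full-run")) {
    surf <- preference_surface(model, grid_spec(cfg$grid$p_min, cfg$grid$p_max,
                                                cfg$grid$step))
    path <- file.path(out_dir, "preference_surface.csv")
    readr::write_csv(tibble::as_tibble(surf), path); emit(path)
    thresholds <- tibble::tibble(
      vary = names(model$strategies),
      threshold = purrr::map_dbl(names(model$strategies),
                                 ~ equal_cost_threshold(model, .x)),
      favored_region_bound = favored_region_bound(model, step = cfg$grid$step)
    )
    path <- file.path(out_dir, "thresholds.csv")
    readr::write_csv(thresholds, path); emit(path)
    if (plots) {
      path <- file.path(out_dir, "preference_surface.png")
      ggplot2::ggsave(path, autoplot(surf), width = 6, height = 5, dpi = 150)
      emit(path)
    }
  }

  sim_path <- file.path(out_dir, "simulated_records.csv")
  if (command %in% c("simulate", "full-run")) {
    trial <- simulate_trial(calibrate_to_targets(), seed = cfg$seed)
    write_patient_records(trial$records, sim_path)
    emit(sim_path)
  }

  if (command %in% c("trial-compare", "full-run")) {
    rp <- records_path %||% sim_path
    records <- read_patient_records(rp)
    cmp <- summarize_arms(records)
    path <- file.path(out_dir, "arm_comparison.csv")
    readr::write_csv(tidy(cmp), path); emit(path)
    path <- file.path(out_dir, "reintervention.csv")
    readr::write_csv(cmp$reintervention, path); emit(path)
    boot <- bootstrap_cost_table(records, n_boot = cfg$bootstrap$n_boot,
                                 seed = cfg$seed,
                                 method = cfg$bootstrap$method,
                                 statistic = cfg$bootstrap$statistic)
    path <- file.path(out_dir, "bootstrap_cis.csv")
    readr::write_csv(boot, path); emit(path)
  }

  manifest <- list(
    package = "biledrain",
    version = as.character(packageVersion("biledrain")),
    command = command,
    seed = cfg$seed,
    config = cfg,
    defaults_relied_on = list(
      beta_rule = cfg$psa$beta_rule,
      bootstrap_statistic = cfg$bootstrap$statistic,
      bootstrap_method = cfg$bootstrap$method,
      grid_step = cfg$grid$step,
      tie_tolerance = TIE_TOLERANCE
    ),
    files = basename(written)
  )
  path <- file.path(out_dir, "manifest.json")
  write_json_report(manifest, path)
  emit(path)
  invisible(written)
}
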