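#' Read and validate a scenario configuration
#'
#' YAML configuration tying the modules into runnable pipelines. Recognised
#' keys: `label`, `parameter_table`, `initial_state`, `p53`
#' (`"wt"`/`"null"`), `plk1_depletion`, `seed`, `solver` (`t_end`, `rtol`,
#' `atol`, `burn_in`), `analysis` (`n_samples`, `alpha_levels`,
#' `depletion_levels`, `n_lines`, `sense`). Unknown top-level keys are
#' rejected.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return Validated config list (class `scenario_config`).
#' @export
read_scenario_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  allowed <- c("label", "parameter_table", "initial_state", "p53",
               "plk1_depletion", "seed", "solver", "analysis")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg$label <- cfg$label %||% "scenario"
  cfg$p53 <- cfg$p53 %||% "wt"
  if (!cfg$p53 %in% c("wt", "null")) {
    stop("config field 'p53' must be \"wt\" or \"null\"", call. = FALSE)
  }
  cfg$plk1_depletion <- cfg$plk1_depletion %||% 0
  if (cfg$plk1_depletion < 0 || cfg$plk1_depletion > 1) {
    stop("config field 'plk1_depletion' must lie in [0, 1]", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$solver <- utils::modifyList(
    list(t_end = 400, rtol = 1e-6, atol = 1e-9, burn_in = 100),
    cfg$solver %||% list())
  cfg$analysis <- utils::modifyList(
    list(n_samples = 200, alpha_levels = seq(0, 1, 0.25),
         depletion_levels = seq(0.1, 1, 0.1), n_lines = 200,
         sense = "log"),
    cfg$analysis %||% list())
  structure(cfg, class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_scenario <- function(cfg) {
  params <- if (!is.null(cfg$parameter_table)) {
    read_parameters(cfg$parameter_table)
  } else default_parameters()
  init <- if (!is.null(cfg$initial_state)) {
    default_initial_state(cfg$initial_state)
  } else default_initial_state()
  scenario_params(cfg$p53, cfg$plk1_depletion, params, init)
}

write_manifest <- function(out_dir, cfg, started, outputs) {
  manifest <- list(
    label = cfg$label,
    seed = cfg$seed,
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("g2mcycle")),
    r_version = R.version.string,
    outputs = outputs,
    wall_time_s = round(as.numeric(Sys.time() - started, units = "secs"), 2))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a pipeline command
#'
#' Deterministic end-to-end runs over the installed model: every command
#' writes machine-readable CSV/JSON outputs plus a manifest recording the
#' configuration, seed, package version and wall time.
#'
#' Commands: `simulate` (trajectory CSV + phenotype JSON), `scan-depletion`
#' (both backgrounds), `scan-limitcycle` (`k_s8` grid by default), `mutants`
#' (deletion-panel phenotype table), `fixture` (synthetic cell-line CSV),
#' `heatmap` (essentiality matrix CSV + PNG), `sense-log`, `sense-prcc`,
#' `sense-fuzzy`.
#'
#' @param config A `scenario_config` (or path to one).
#' @param command Pipeline command (see Details).
#' @param out_dir Output directory (created if missing).
#' @return Invisible list of written file paths.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "scan-depletion",
                                     "scan-limitcycle", "mutants",
                                     "fixture", "heatmap", "sense-log",
                                     "sense-prcc", "sense-fuzzy"),
                         out_dir = ".") {
  command <- match.arg(command)
  cfg <- if (inherits(config, "scenario_config")) config
         else read_scenario_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- Sys.time()
  sc <- config_scenario(cfg)
  outputs <- character(0)
  message(sprintf("[g2mcycle] %s: %s", command, sc$label))

  w <- function(obj, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  if (command == "simulate") {
    sim <- simulate_cycle(sc$params, init = sc$init,
                          t_end = cfg$solver$t_end,
                          rtol = cfg$solver$rtol, atol = cfg$solver$atol)
    w(tidy(sim), "trajectory.csv")
    ph <- classify_phenotype(sim, wt_reference()$period,
                             burn_in = cfg$solver$burn_in)
    path <- file.path(out_dir, "phenotype.json")
    jsonlite::write_json(as.list(ph), path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path)
  } else if (command == "scan-depletion") {
    for (bg in c("p53-wt", "p53-null")) {
      scan <- plk1_depletion_scan(bg, cfg$analysis$depletion_levels,
                                  params = if (bg == "p53-null")
                                    default_parameters() else sc$params)
      w(scan, paste0("depletion_", bg, ".csv"))
    }
  } else if (command == "scan-limitcycle") {
    grid <- seq(0.5, 1.5, by = 0.1) * sc$params[["k_s8"]]
    rng <- limit_cycle_range(sc$params, "k_s8", grid)
    w(rng$detail, "limitcycle_k_s8.csv")
  } else if (command == "mutants") {
    w(mutant_table(params = sc$params), "mutant_table.csv")
  } else if (command == "fixture") {
    lines <- simulate_cell_lines(cfg$analysis$n_lines, seed = cfg$seed)
    w(lines, "cell_lines.csv")
    groups <- group_cell_lines(lines)
    w(dplyr::mutate(groups,
                    genes = purrr::map_chr(.data$genes, paste,
                                           collapse = "+")),
      "cell_line_groups.csv")
  } else if (command == "heatmap") {
    lines <- simulate_cell_lines(cfg$analysis$n_lines, seed = cfg$seed)
    groups <- group_cell_lines(lines)
    em <- essentiality_matrix(groups, params = sc$params)
    w(em, "essentiality_matrix.csv")
    plot_path <- file.path(out_dir, "essentiality_heatmap.png")
    grDevices::png(plot_path, width = 1200, height = 800, res = 130)
    print(ggplot2::autoplot(em))
    grDevices::dev.off()
    outputs <- c(outputs, plot_path)
  } else if (command == "sense-log") {
    rep <- log_sensitivity(sc$params, init = sc$init, scenario = sc$label)
    w(rep$values, "sensitivity_log.csv")
    w(average_log_sensitivity(rep), "sensitivity_log_means.csv")
  } else if (command == "sense-prcc") {
    rep <- prcc_analysis(sc$params, n_samples = cfg$analysis$n_samples,
                         seed = cfg$seed, init = sc$init,
                         scenario = sc$label)
    w(tidy(rep), "sensitivity_prcc.csv")
  } else if (command == "sense-fuzzy") {
    rep <- fuzzy_analysis(sc$params,
                          alpha_levels = cfg$analysis$alpha_levels,
                          init = sc$init, scenario = sc$label)
    w(tibble::as_tibble(rep), "sensitivity_fuzzy.csv")
  }
  write_manifest(out_dir, cfg, started, outputs)
  invisible(c(outputs, file.path(out_dir, "manifest.json")))
}
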