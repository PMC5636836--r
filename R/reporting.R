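#' Run configuration
#'
#' A plain nested list (YAML-compatible) describing a full pipeline run:
#' a top-level seed, an optional \code{synthetic} block of
#' [sampling_config()] overrides (or \code{inputs} paths to existing CSV
#' tables), and a list of scenario blocks. The default configuration runs
#' the six standard scenarios: diet variants 1-3 crossed with abundance
#' scenarios N1 (562 +/- 71) and N2 (1130 +/- 137).
#'
#' @param seed Top-level integer seed.
#' @param n_sims Monte Carlo draws per scenario.
#' @return Nested list.
#' @export
default_run_config <- function(seed = 1, n_sims = 1000) {
  scen <- list()
  for (v in 1:3) {
    for (ab in c("N1", "N2")) {
      scen[[paste0("M", v, ab)]] <-
        list(diet_variant = v, abundance = ab, n_sims = n_sims)
    }
  }
  list(seed = seed, synthetic = list(), scenarios = scen)
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file in the [default_run_config()] layout.
#' @return Nested list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$scenarios)) cfg$scenarios <- default_run_config()$scenarios
  cfg
}

sampling_config_from_list <- function(lst, seed) {
  args <- lst
  if (!is.null(args$target_fo)) args$target_fo <- unlist(args$target_fo)
  for (f in c("predator_mass_range", "predator_tl_range",
              "digested_fraction_range", "season_temps_c")) {
    if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
  }
  args$seed <- seed
  do.call(sampling_config, args)
}

scenario_config_from_list <- function(lst, seed) {
  scenario_config(
    diet_variant = lst$diet_variant,
    abundance = if (is.list(lst$abundance)) {
      abundance_scenario(lst$abundance$label %||% "custom",
                         mean = lst$abundance$mean, sd = lst$abundance$sd)
    } else abundance_scenario(lst$abundance %||% "N2"),
    n_sims = lst$n_sims %||% 1000,
    uncertainty = lst$uncertainty %||% list(),
    focal_species = lst$focal_species %||% "gummy_shark",
    focal_fraction = if (!is.null(lst$focal_fraction)) lst$focal_fraction
      else if (isTRUE(lst$estimate_focal_fraction)) NULL else 0.25,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

write_manifest <- function(dir, command, seed, config, extra = list()) {
  manifest <- c(list(command = command, seed = seed,
                     config_hash = config_hash(config), config = config),
                extra)
  path <- file.path(dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Generate the synthetic CSV bundle
#'
#' Writes \code{predators.csv}, \code{stomachs.csv} and
#' \code{prey_survey.csv} (UTF-8, header row, full precision) plus a
#' manifest recording the seed, the configuration and its hash, so the run
#' can be reproduced exactly with [rerun_from_manifest()].
#'
#' @param config Run configuration list (see [default_run_config()]); its
#'   \code{synthetic} block holds [sampling_config()] overrides.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed; defaults to \code{config$seed}.
#' @return Invisibly, the written file paths.
#' @export
cmd_generate <- function(config = default_run_config(), out_dir = ".",
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sampling_config_from_list(config$synthetic %||% list(), seed)
  profiles <- prey_profiles()
  predators <- generate_predators(cfg)
  stomachs <- generate_stomachs(cfg, profiles)
  survey <- generate_prey_survey(cfg, profiles)
  paths <- c(
    write_table(predators, file.path(out_dir, "predators.csv")),
    write_table(stomachs, file.path(out_dir, "stomachs.csv")),
    write_table(survey, file.path(out_dir, "prey_survey.csv")),
    write_manifest(out_dir, "generate", seed, config,
                   list(n_stomachs = attr(stomachs, "n_stomachs"))))
  invisible(paths)
}

load_inputs <- function(config, seed) {
  profiles <- if (!is.null(config$inputs$profiles)) {
    prey_profiles(config$inputs$profiles)
  } else prey_profiles()
  if (!is.null(config$inputs$predators)) {
    predators <- utils::read.csv(config$inputs$predators)
    stomachs <- utils::read.csv(config$inputs$stomachs)
    attr(stomachs, "n_stomachs") <- config$inputs$n_stomachs %||%
      length(unique(stomachs$shark_id))
  } else {
    cfg <- sampling_config_from_list(config$synthetic %||% list(), seed)
    predators <- generate_predators(cfg)
    stomachs <- generate_stomachs(cfg, profiles)
  }
  missing_sp <- setdiff(unique(stomachs$species), profiles$species)
  if (length(missing_sp)) {
    stop("no prey profile for species present in stomach records: ",
         paste(missing_sp, collapse = ", "))
  }
  list(predators = predators, stomachs = stomachs, profiles = profiles)
}

#' Run the configured scenarios and write the results bundle
#'
#' Runs every scenario block in the configuration and writes
#' \code{results.csv} (one row per scenario x prey species, in the standard
#' 13-species layout: variant-1 scenarios report only the focal species,
#' other cells are NA), \code{draws.csv} (per-simulation counts), and a
#' manifest.
#'
#' @inheritParams cmd_generate
#' @return Invisibly, a list of \code{"scenario_result"} objects.
#' @export
cmd_simulate <- function(config = default_run_config(), out_dir = ".",
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config, seed)
  labels <- names(config$scenarios)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("scenario blocks must have unique labels")
  }
  sseeds <- derive_seeds(seed, labels)
  all_species <- inp$profiles$species[inp$profiles$group != "predator"]
  results <- list()
  res_rows <- list()
  draw_rows <- list()
  for (lab in labels) {
    scfg <- scenario_config_from_list(config$scenarios[[lab]], sseeds[[lab]])
    res <- run_scenario(scfg, inp$predators, inp$stomachs, inp$profiles)
    results[[lab]] <- res
    tab <- data.frame(scenario = lab, species = all_species)
    tab <- merge(tab, res$summary, by = "species", all.x = TRUE, sort = FALSE)
    tab <- tab[match(all_species, tab$species),
               c("scenario", "species", "mean_count", "ci_low", "ci_high",
                 "biomass_t")]
    res_rows[[lab]] <- tab
    draw_rows[[lab]] <- data.frame(
      scenario = lab,
      sim = rep(seq_len(nrow(res$draws)), ncol(res$draws)),
      species = rep(colnames(res$draws), each = nrow(res$draws)),
      count = as.vector(res$draws))
  }
  write_table(do.call(rbind, res_rows), file.path(out_dir, "results.csv"))
  write_table(do.call(rbind, draw_rows), file.path(out_dir, "draws.csv"))
  write_manifest(out_dir, "simulate", seed, config)
  invisible(results)
}

#' Run a sensitivity sweep and write sensitivity.csv
#'
#' @inheritParams cmd_generate
#' @param axis \code{"temperature"}, \code{"q10"} or \code{"abundance"}.
#' @param grid Numeric grid of parameter values.
#' @param scenario Label of the scenario block to sweep (default the
#'   first).
#' @return Invisibly, the sweep data frame.
#' @export
cmd_sensitivity <- function(config = default_run_config(), axis, grid,
                            out_dir = ".", seed = config$seed,
                            scenario = names(config$scenarios)[1]) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config, seed)
  if (!scenario %in% names(config$scenarios)) {
    stop("unknown scenario label '", scenario, "'")
  }
  scfg <- scenario_config_from_list(config$scenarios[[scenario]],
                                    derive_seeds(seed, scenario)[[1]])
  sw <- sensitivity_sweep(scfg, inp$predators, inp$stomachs, inp$profiles,
                          axis = axis, grid = grid)
  write_table(sw, file.path(out_dir, "sensitivity.csv"))
  write_manifest(out_dir, "sensitivity", seed, config,
                 list(axis = axis, grid = grid, scenario = scenario))
  invisible(sw)
}

#' Validate a profile table from the command line
#'
#' @param file Profile CSV (default the packaged table).
#' @param corrected Use corrected coefficients (see [prey_profiles()]).
#' @param out Optional path to write the validation report CSV.
#' @return The [validate_profiles()] report.
#' @export
cmd_validate_profiles <- function(file = NULL, corrected = TRUE, out = NULL) {
  rep <- validate_profiles(prey_profiles(file, corrected = corrected))
  if (!is.null(out)) write_table(rep, out)
  rep
}

#' Re-run a command from its manifest
#'
#' Reads a manifest written by [cmd_generate()], [cmd_simulate()] or
#' [cmd_sensitivity()] and re-executes the command with the recorded seed
#' and configuration; outputs are byte-identical to the original run.
#'
#' @param manifest_path Path to a \code{manifest_*.json} file.
#' @param out_dir Directory for the reproduced outputs.
#' @return Invisibly, whatever the underlying command returns.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  config <- m$config
  switch(m$command,
         generate = cmd_generate(config, out_dir, seed = m$seed),
         simulate = cmd_simulate(config, out_dir, seed = m$seed),
         sensitivity = cmd_sensitivity(config, axis = m$axis,
                                       grid = unlist(m$grid),
                                       out_dir = out_dir, seed = m$seed,
                                       scenario = m$scenario),
         stop("unknown command '", m$command, "' in manifest"))
}
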