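#' Default run configuration
#'
#' Configuration for the pipeline subcommands, as a named list.  Values can
#' come from a YAML file ([read_run_config()]) and/or be overridden
#' programmatically; precedence is overrides > file > defaults.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    pedigree = "pedigree.csv",
    records = "records.csv",
    out_dir = "equigen-run",
    model = "A",
    category = NULL,
    distance_category = NULL,
    n_iter = 6000, burn_in = 1000, thin = 5,
    n_sim = 1000,
    first = 1995, last = 2012,
    seed = 1,
    beta_P = NULL,
    sim = list()
  )
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    abort("run_config() overrides must be named")
  }
  cfg <- modifyList(defaults, over)
  if (cfg$first > cfg$last) abort("cohort window is not well ordered")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of configuration keys; see [run_config()].
#' @param ... Further overrides applied on top of the file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, modifyList(vals %||% list(), list(...)))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, out_dir, artifacts) {
  manifest <- list(
    package = "equigen",
    version = as.character(packageVersion("equigen")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    config = unclass(cfg),
    artifacts = artifacts
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

#' Run one pipeline subcommand
#'
#' Orchestrates the analysis stages over files on disk.  Subcommands:
#' `simulate` (write a synthetic pedigree/record pair plus ground-truth
#' sidecar), `fit` (REML + Gibbs animal model; writes variance components,
#' fixed effects, breeding values and posterior draws), `trend` (cohort
#' means and the beta_G posterior), `drift` (gene-dropping test), and
#' `selection` (generation interval, realised intensity and implied
#' selected proportion), `summarize` (pedigree/record summary tables).
#' Every invocation writes a `manifest.yaml` naming the seed and config
#' hash.  On error, partial outputs of the failed stage are removed.
#'
#' @param name Subcommand name.
#' @param cfg A [run_config()].
#' @return Invisibly, a named list of artifact paths.
#' @export
run_subcommand <- function(name = c("simulate", "fit", "trend", "drift",
                                    "selection", "summarize"),
                           cfg = run_config()) {
  name <- match.arg(name)
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- list.files(out_dir, full.names = TRUE)
  res <- tryCatch(
    switch(name,
      simulate = cmd_simulate(cfg),
      fit = cmd_fit(cfg),
      trend = cmd_trend(cfg),
      drift = cmd_drift(cfg),
      selection = cmd_selection(cfg),
      summarize = cmd_summarize(cfg)
    ),
    error = function(e) {
      fresh <- setdiff(list.files(out_dir, full.names = TRUE), started)
      unlink(fresh, recursive = TRUE)
      abort(paste0("subcommand '", name, "' failed: ",
                   conditionMessage(e)))
    }
  )
  write_manifest(cfg, out_dir, res)
  invisible(res)
}

load_inputs <- function(cfg) {
  ped <- read_pedigree(cfg$pedigree)
  category <- cfg$category %||% cfg$distance_category
  records <- read_records(cfg$records, category = category)
  ped <- trim_pedigree(ped, unique(records$horse))
  list(ped = ped, records = records)
}

cmd_simulate <- function(cfg) {
  sim_args <- cfg$sim %||% list()
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_horse_data(scfg, seed = cfg$seed)
  out <- cfg$out_dir
  paths <- list(
    pedigree = file.path(out, "pedigree.csv"),
    records = file.path(out, "records.csv"),
    true_bv = file.path(out, "true_bv.csv"),
    truth = file.path(out, "truth.yaml")
  )
  write_pedigree(sim$ped, paths$pedigree)
  write_records(sim$records, paths$records)
  readr::write_csv(tibble(id = names(sim$true_bv),
                          true_bv = unname(sim$true_bv)), paths$true_bv)
  yaml::write_yaml(sim$truth[c("V_A", "V_PE", "V_T", "V_R", "V_P", "h2",
                               "repeatability")], paths$truth)
  paths
}

cmd_fit <- function(cfg) {
  inp <- load_inputs(cfg)
  des <- build_design(inp$records, model_spec(cfg$model), inp$ped)
  fit <- fit_reml(des, inp$ped)
  g <- fit_gibbs(des, inp$ped,
                 chain = chain_plan(cfg$n_iter, cfg$burn_in, cfg$thin),
                 seed = derive_seed(cfg$seed, "gibbs"))
  out <- cfg$out_dir
  paths <- list(
    variance_components = file.path(out, "variance_components.csv"),
    fixed_effects = file.path(out, "fixed_effects.csv"),
    pbv = file.path(out, "pbv.csv"),
    vc_draws = file.path(out, "vc_draws.csv"),
    bv_draws = file.path(out, "bv_draws.csv"),
    diagnostics = file.path(out, "diagnostics.csv"),
    report = file.path(out, "fit_report.txt")
  )
  readr::write_csv(tidy(fit), paths$variance_components)
  readr::write_csv(fit$fixed_effects, paths$fixed_effects)
  by <- setNames(inp$ped$birth_year, inp$ped$id)
  readr::write_csv(tibble(id = names(fit$pbv), pbv = unname(fit$pbv),
                          birth_year = unname(by[names(fit$pbv)])),
                   paths$pbv)
  readr::write_csv(as_tibble(g$vc_draws), paths$vc_draws)
  readr::write_csv(as_tibble(g$bv_draws, .name_repair = "minimal"),
                   paths$bv_draws)
  readr::write_csv(diagnostics(g), paths$diagnostics)
  con <- file(paths$report, "w")
  sink(con)
  print(fit)
  print(g)
  sink()
  close(con)
  paths
}

read_fit_outputs <- function(cfg) {
  out <- cfg$out_dir
  vcd <- as.matrix(readr::read_csv(file.path(out, "vc_draws.csv"),
                                   show_col_types = FALSE))
  bvd <- as.matrix(readr::read_csv(file.path(out, "bv_draws.csv"),
                                   show_col_types = FALSE,
                                   name_repair = "minimal"))
  inp <- load_inputs(cfg)
  structure(
    list(vc_draws = vcd, bv_draws = bvd,
         chain = list(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                      thin = cfg$thin, n_retained = nrow(vcd),
                      seed = derive_seed(cfg$seed, "gibbs")),
         ped_ids = colnames(bvd), horse_ids = unique(inp$records$horse),
         model = cfg$model),
    class = "equigen_gibbs"
  )
}

cmd_trend <- function(cfg) {
  inp <- load_inputs(cfg)
  g <- read_fit_outputs(cfg)
  if (!identical(g$ped_ids, inp$ped$id)) {
    abort("stored breeding-value draws do not match the trimmed pedigree")
  }
  tr <- beta_g_posterior(g, inp$ped, cfg$first, cfg$last,
                         beta_P = cfg$beta_P)
  out <- cfg$out_dir
  paths <- list(
    cohort_means = file.path(out, "cohort_means.csv"),
    trend = file.path(out, "trend.yaml"),
    figure = file.path(out, "trend.pdf")
  )
  readr::write_csv(tidy(tr), paths$cohort_means)
  yaml::write_yaml(lapply(as.list(glance(tr)), unname), paths$trend)
  grDevices::pdf(paths$figure, width = 7, height = 4.5)
  print(autoplot(tr))
  grDevices::dev.off()
  paths
}

cmd_drift <- function(cfg) {
  inp <- load_inputs(cfg)
  g <- read_fit_outputs(cfg)
  tr <- beta_g_posterior(g, inp$ped, cfg$first, cfg$last)
  dr <- run_drift_test(g, tr, inp$ped, n_sim = cfg$n_sim,
                       seed = derive_seed(cfg$seed, "drift"))
  out <- cfg$out_dir
  paths <- list(
    drift_slopes = file.path(out, "drift_slopes.csv"),
    drift = file.path(out, "drift.yaml")
  )
  readr::write_csv(tidy(dr), paths$drift_slopes)
  yaml::write_yaml(lapply(as.list(glance(dr)), unname), paths$drift)
  paths
}

cmd_selection <- function(cfg) {
  inp <- load_inputs(cfg)
  des <- build_design(inp$records, model_spec(cfg$model), inp$ped)
  fit <- fit_reml(des, inp$ped, se = FALSE)
  tr <- trend_from_reml(fit, inp$ped, cfg$first, cfg$last,
                        beta_P = cfg$beta_P)
  sel <- selection_summary(fit, tr, inp$ped, inp$records)
  out <- cfg$out_dir
  paths <- list(selection = file.path(out, "selection.csv"))
  readr::write_csv(sel, paths$selection)
  paths
}

cmd_summarize <- function(cfg) {
  inp <- load_inputs(cfg)
  out <- cfg$out_dir
  paths <- list(
    pedigree_summary = file.path(out, "pedigree_summary.csv"),
    record_summary = file.path(out, "record_summary.csv")
  )
  readr::write_csv(summarize_pedigree(inp$ped, inp$records),
                   paths$pedigree_summary)
  rs <- inp$records |>
    group_by(.data$category) |>
    summarise(
      n_records = dplyr::n(),
      n_horses = dplyr::n_distinct(.data$horse),
      n_races = dplyr::n_distinct(.data$race_id),
      mean_speed = mean(.data$speed),
      mean_records_per_horse = dplyr::n() / dplyr::n_distinct(.data$horse),
      .groups = "drop"
    )
  readr::write_csv(rs, paths$record_summary)
  paths
}
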