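#' Pipeline configuration
#'
#' One object holding everything [run_full_pipeline()] needs. Exactly one
#' data source per stage: either `input_dir` (CSV schemas of
#' [read_survey_tables()]) or the synthetic-generation parameters. All
#' randomness flows from `seed`, expanded deterministically into per-stage
#' and per-chain seeds.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Global integer seed.
#' @param input_dir Optional directory of input CSVs; `NULL` simulates.
#' @param truth [truth_params()] for the synthetic living/DOR stages.
#' @param n_sites,n_dor,n_risk_per_group Synthetic sizes.
#' @param risk [risk_truth()] for the synthetic risk stage.
#' @param citizen Length-4 counts `(total_melanic, dead_melanic,
#'   total_gray, dead_gray)` used when no citizen table is read.
#' @param mcmc An [mcmc_config()] (its seeds are re-derived from `seed`).
#'   The default is a reduced protocol sized for routine synthetic runs;
#'   pass `mcmc_config()` for the full field protocol.
#' @param living_priors,dor_priors Prior overrides.
#' @param grid_km Distance grid for the curves.
#' @param exposures Risk exposures to estimate.
#' @param dag DAG for risk adjustment.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, input_dir = NULL,
                            truth = truth_params(), n_sites = 41,
                            n_dor = 141, n_risk_per_group = 141,
                            risk = risk_truth(),
                            citizen = c(12705, 174, 96025, 1581),
                            mcmc = mcmc_config(n_chains = 3, n_adapt = 1000,
                                               n_iter = 2500, n_burnin = 500,
                                               thin = 2),
                            living_priors = default_living_priors(),
                            dor_priors = default_dor_priors(),
                            grid_km = distance_grid(),
                            exposures = c("speed", "traffic", "crossings",
                                          "habitat_split"),
                            dag = default_squirrel_dag(),
                            verbose = TRUE) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), input_dir = input_dir,
         truth = truth, n_sites = n_sites, n_dor = n_dor,
         n_risk_per_group = n_risk_per_group, risk = risk,
         citizen = citizen, mcmc = mcmc, living_priors = living_priors,
         dor_priors = dor_priors, grid_km = grid_km, exposures = exposures,
         dag = dag, verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

pipe_log <- function(config, stage, ...) {
  if (config$verbose) message("[", stage, "] ", ...)
}

run_stage <- function(config, stage, expr) {
  pipe_log(config, stage, "start")
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage `", stage, "` failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full simulate/fit/contrast/risk/table-stats workflow
#'
#' Orchestrates the whole analysis: obtain data (synthetic or from CSVs),
#' fit the living-squirrel and DOR cline models by MCMC, summarize the
#' posterior with 95% credible intervals and split-chain R-hat, derive the
#' living/DOR cline curves and their posterior difference over the distance
#' grid, estimate DAG-adjusted Firth effects of each risk exposure, and
#' compute the citizen-science contingency statistics. All outputs are
#' written under `config$out_dir`; re-running with the same config and seed
#' reproduces every numeric output.
#'
#' @param config A [pipeline_config()].
#' @return A report list (fits, summary tibble, contrast curves, risk
#'   effects, citizen stats, R-hat vector, convergence flag, file paths),
#'   invisibly writable via its `files` element.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 5)

  data <- run_stage(config, "data", {
    if (!is.null(config$input_dir)) {
      read_survey_tables(config$input_dir)
    } else {
      list(
        survey = simulate_squirrel_surveys(config$truth, config$n_sites,
                                           seed = seeds[1]),
        dor = simulate_dor_records(config$truth, config$n_dor, seeds[2]),
        risk = simulate_risk_dataset(config$risk, config$n_risk_per_group,
                                     seeds[3])
      )
    }
  })
  citizen <- data$citizen %||% make_citizen_table(
    config$citizen[1], config$citizen[2], config$citizen[3], config$citizen[4])

  living <- run_stage(config, "fit-cline", {
    cfg <- config$mcmc
    cfg$seeds <- derive_seeds(seeds[4], cfg$n_chains)
    fit_living_model(data$survey, cfg, config$living_priors)
  })
  dor <- run_stage(config, "fit-dor", {
    cfg <- config$mcmc
    cfg$seeds <- derive_seeds(seeds[5], cfg$n_chains)
    fit_dor_model(data$dor, cfg, config$dor_priors)
  })

  rhat <- c(gelman_rubin(living), gelman_rubin(dor))
  converged <- all(rhat < 1.1)
  if (!converged) {
    warn(paste0("R-hat >= 1.1 for: ",
                paste(names(rhat)[rhat >= 1.1], collapse = ", ")))
  }
  summary_tbl <- dplyr::bind_rows(
    dplyr::mutate(tidy(living), model = "living", .before = 1),
    dplyr::mutate(tidy(dor), model = "dor", .before = 1)
  )
  summary_tbl$excludes_zero <- summary_tbl$lower95 > 0 | summary_tbl$upper95 < 0

  contrast <- run_stage(config, "contrast",
                        cline_difference_curves(living, dor, config$grid_km))

  risk_effects <- run_stage(config, "fit-risk", {
    lapply(setNames(config$exposures, config$exposures), function(ex) {
      estimate_risk_effect(data$risk, ex, dag = config$dag)
    })
  })
  citizen_stats <- run_stage(config, "table-stats", morph_mortality_test(citizen))

  files <- c(
    posterior_living = file.path(config$out_dir, "posterior_living.csv"),
    posterior_dor = file.path(config$out_dir, "posterior_dor.csv"),
    summary = file.path(config$out_dir, "summary_table.csv"),
    curve_living = file.path(config$out_dir, "curve_living.csv"),
    curve_dor = file.path(config$out_dir, "curve_dor.csv"),
    curve_difference = file.path(config$out_dir, "curve_difference.csv"),
    risk_effects = file.path(config$out_dir, "risk_effects.json"),
    citizen_stats = file.path(config$out_dir, "citizen_stats.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write.csv(as.data.frame(as_draws_df(living)), files[["posterior_living"]],
            row.names = FALSE)
  write.csv(as.data.frame(as_draws_df(dor)), files[["posterior_dor"]],
            row.names = FALSE)
  write.csv(as.data.frame(summary_tbl), files[["summary"]], row.names = FALSE)
  write_curve(contrast$living, files[["curve_living"]])
  write_curve(contrast$dor, files[["curve_dor"]])
  write_curve(contrast$difference, files[["curve_difference"]])
  jsonlite::write_json(
    lapply(risk_effects, function(r) {
      list(exposure = r$exposure, estimate = r$estimate, se = r$se,
           p_value = r$p_value, adjustment = as.list(r$adjustment),
           log_transformed = as.list(r$log_transformed))
    }),
    files[["risk_effects"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(citizen_stats), files[["citizen_stats"]],
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("roadcline")),
         seed = config$seed, stage_seeds = as.list(seeds),
         mcmc = config$mcmc[c("n_chains", "n_adapt", "n_iter", "n_burnin",
                              "thin", "n_retained")],
         synthetic = is.null(config$input_dir),
         n_sites = config$n_sites, n_dor = config$n_dor,
         n_risk_per_group = config$n_risk_per_group,
         rhat = as.list(rhat), converged = converged),
    files[["manifest"]], auto_unbox = TRUE, digits = NA)
  pipe_log(config, "done", "outputs in ", config$out_dir)

  invisible(list(living_fit = living, dor_fit = dor, summary = summary_tbl,
                 contrast = contrast, risk = risk_effects,
                 citizen = citizen_stats, rhat = rhat, converged = converged,
                 data = data, files = files, config = config))
}
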