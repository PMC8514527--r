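#' Configure an end-to-end pipeline run
#'
#' Collects every tunable choice of the pipeline with its documented
#' default.  Inputs are either a synthetic-world configuration
#' (`synthetic`) or the four input tables (tibbles, or paths to CSV files
#' in the package schemas).  Unknown options are rejected.
#'
#' @param synthetic A [sim_config()] to generate all inputs, or `NULL` to
#'   use the supplied tables/paths.
#' @param covariates,responses,warming,income Input tables or CSV paths
#'   (ignored when `synthetic` is given).
#' @param output_dir Directory for the output CSVs and run log; `NULL`
#'   skips writing.
#' @param loocv_unit Cross-validation unit, `"country"` (default) or
#'   `"observation"`.
#' @param ssc Small-sample correction of the clustered covariance
#'   (`"CR1"`, `"none"`, or a number).
#' @param ci_level Confidence level for all intervals (default 0.95).
#' @param quantile CI reference distribution, `"z"` (default) or `"t"`
#'   (Student t on G - 1 degrees of freedom).
#' @param weight_scheme Global aggregation weights, `"baseline_deaths"`
#'   (default) or `"population"`.
#' @param period_years Midpoint calendar years of the `mid` and `end`
#'   projection periods, used to evaluate projected income.
#' @param preindustrial_offset Degrees C between the 2001-2020 baseline and
#'   preindustrial, for the curve's secondary axis.
#' @param curve_grid Global-warming grid of the response curve.
#' @param seed Seed governing every random draw of a synthetic run.
#' @param ... Unknown options — always an error, so typos never pass
#'   silently.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            covariates = NULL, responses = NULL,
                            warming = NULL, income = NULL,
                            output_dir = NULL,
                            loocv_unit = c("country", "observation"),
                            ssc = "CR1",
                            ci_level = 0.95,
                            quantile = c("z", "t"),
                            weight_scheme = c("baseline_deaths",
                                              "population"),
                            period_years = c(mid = 2055, end = 2090),
                            preindustrial_offset = 1.0,
                            curve_grid = seq(0, 5, by = 0.1),
                            seed = 42L, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort_climmort("unknown configuration option(s): %s",
                   paste(names(extra), collapse = ", "))
  }
  if (is.null(synthetic) && is.null(covariates)) {
    abort_climmort("supply either 'synthetic' or input tables")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "sim_config"))
  structure(
    list(synthetic = synthetic, covariates = covariates,
         responses = responses, warming = warming, income = income,
         output_dir = output_dir,
         loocv_unit = match.arg(loocv_unit), ssc = ssc,
         ci_level = assert_number(ci_level, "ci_level", 0, 1),
         quantile = match.arg(quantile),
         weight_scheme = match.arg(weight_scheme),
         period_years = period_years,
         preindustrial_offset = preindustrial_offset,
         curve_grid = curve_grid, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

resolve_table <- function(x, reader) {
  if (is.null(x) || is.data.frame(x)) return(x)
  reader(x)
}

#' Run the full damage-function pipeline
#'
#' Composes every stage: input loading (or synthetic generation), model
#' selection for both outcomes, fitting the preferred specifications,
#' projecting all countries for every scenario x period with and without
#' income-based adaptation, global aggregation, and the warming-response
#' curve.  All settings are echoed to the run log, missing countries are
#' reported explicitly, and a given config with given inputs always yields
#' identical output.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list of class `climmort_run`: `covariates`,
#'   `responses`, `warming`, `income`, `validation` (heat and cold
#'   validation tables), `fits`, `projections`, `missing`, `global`,
#'   `curve`, `config`, `log` (character vector, also written to
#'   `output_dir/run_log.txt` together with the output CSVs when
#'   `output_dir` is set).
#' @export
#' @examples
#' run <- run_pipeline(pipeline_config(synthetic = sim_config(
#'   n_countries = 8, seed = 11)), quiet = TRUE)
#' run$global
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) message(line)
    invisible(NULL)
  }
  say("climmort pipeline (schema %s)", CLIMMORT_SCHEMA_VERSION)
  for (opt in c("loocv_unit", "ssc", "ci_level", "quantile",
                "weight_scheme", "preindustrial_offset", "seed")) {
    say("option %s = %s", opt, paste(format(config[[opt]]), collapse = ", "))
  }
  say("option period_years = mid:%d end:%d",
      config$period_years[["mid"]], config$period_years[["end"]])

  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    sc$seed <- config$seed
    say("inputs: synthetic world (%d countries, seed %d)",
        sc$n_countries, sc$seed)
    covariates <- sim_world(sc)
    warming <- sim_warming(covariates, sc)
    responses <- sim_response_table(covariates, warming, sc)
    income <- sim_income_paths(covariates, seed = sc$seed + 4L)
  } else {
    say("inputs: user-supplied tables")
    covariates <- resolve_table(config$covariates, read_covariates)
    responses <- resolve_table(config$responses, read_responses)
    warming <- resolve_table(config$warming, read_warming)
    income <- resolve_table(config$income, read_income)
    validate_bundle(covariates, responses, warming, income)
  }
  if (!"log_gdp_pc" %in% names(covariates)) {
    covariates$log_gdp_pc <- log(covariates$gdp_pc_ppp)
  }

  validation <- fits <- list()
  for (outcome in c("heat", "cold")) {
    v <- select_damage_model(responses, covariates, outcome,
                             unit = config$loocv_unit, ssc = config$ssc)
    validation[[outcome]] <- v
    fits[[outcome]] <- preferred_fit(v)
    say("%s outcome: model %d preferred (LOOCV rmse %.3f)",
        outcome, v$model[v$rank == 1], min(v$cv_rmse))
  }

  proj <- list()
  for (adapt in c(FALSE, TRUE)) {
    if (adapt && is.null(income)) {
      say("no income paths: skipping adaptation projections")
      next
    }
    proj[[length(proj) + 1]] <- project_mortality(
      fits$heat, fits$cold, covariates, warming,
      adaptation = adapt, income_paths = income,
      period_years = config$period_years,
      level = config$ci_level, quantile = config$quantile)
  }
  projections <- dplyr::bind_rows(proj)
  attr(projections, "fits") <- attr(proj[[1]], "fits")
  attr(projections, "level") <- config$ci_level
  attr(projections, "quantile") <- config$quantile
  projections <- tibble::new_tibble(projections,
                                    class = "mortality_projection")
  missing <- dplyr::bind_rows(lapply(proj, missing_report))
  attr(projections, "missing") <- missing
  say("projected %d rows; %d missing rows reported",
      nrow(projections), nrow(missing))

  global <- global_rate_change(projections, covariates,
                               weight_scheme = config$weight_scheme,
                               level = config$ci_level,
                               quantile = config$quantile)
  ratios <- attr(warming, "ratios") %||% pattern_ratios(warming)
  curve <- warming_response_curve(
    fits$heat, fits$cold, covariates, ratios,
    global_dT = config$curve_grid, adaptation = FALSE,
    weight_scheme = config$weight_scheme,
    level = config$ci_level, quantile = config$quantile,
    preindustrial_offset = config$preindustrial_offset)
  say("aggregated %d scenario x period x adaptation cells; curve on %d grid points",
      nrow(global), nrow(curve))

  out <- list(covariates = covariates, responses = responses,
              warming = warming, income = income,
              validation = validation, fits = fits,
              projections = projections, missing = missing,
              global = global, curve = curve,
              config = config, log = log)
  class(out) <- "climmort_run"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(config$output_dir, f)
    write_climmort_csv(covariates, pth("covariates.csv"), "covariates")
    write_climmort_csv(responses, pth("responses.csv"), "responses")
    write_climmort_csv(warming, pth("warming.csv"), "warming")
    if (!is.null(income)) {
      write_climmort_csv(income, pth("income.csv"), "income")
    }
    for (outcome in c("heat", "cold")) {
      readr::write_csv(tibble::as_tibble(validation[[outcome]]),
                       pth(sprintf("validation_%s.csv", outcome)),
                       progress = FALSE)
    }
    write_climmort_csv(tibble::as_tibble(projections),
                       pth("projections.csv"), "projections")
    write_climmort_csv(global, pth("global_summary.csv"), "global_summary")
    write_climmort_csv(curve, pth("curve.csv"), "curve")
    readr::write_csv(missing, pth("missing_report.csv"), progress = FALSE)
    writeLines(log, pth("run_log.txt"))
    out$log <- log
  }
  invisible(out)
}

#' @export
print.climmort_run <- function(x, ...) {
  cat("<climmort_run>\n")
  cat(sprintf("  %d countries, %d response rows\n",
              nrow(x$covariates), nrow(x$responses)))
  cat(sprintf("  preferred models: heat %d, cold %d\n",
              x$fits$heat$spec$model, x$fits$cold$spec$model))
  cat(sprintf("  %d projection rows (%d missing), %d global cells\n",
              nrow(x$projections), nrow(x$missing), nrow(x$global)))
  invisible(x)
}
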