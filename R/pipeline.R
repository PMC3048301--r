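#' Run the full virtual-population policy simulation
#'
#' One call wires the stages together: generate the stratified virtual
#' population, score every individual's 10-year fatal cardiovascular
#' risk, apply the requested eligibility scenarios, and compute the
#' impact summaries.  This is the programmatic core behind
#' [run_pipeline()].
#'
#' @param config a [population_config()]; default the shipped
#'   calibration.
#' @param scenarios subset of `c("I", "II", "III")`.
#' @param rr treatment relative risk (default 0.83).
#' @param coeffs SCORE coefficients.
#' @param n_per_stratum optional fixed stratum size (overrides the
#'   `size * sample_fraction` rule; useful for quick runs).
#' @param n_reps if `>= 2`, also run [replicate_impact()] with this many
#'   replicate populations per scenario.
#' @return An object of class `rvp_sim` with elements `population`
#'   (scored), `decisions`, `impacts` (one `rvp_impact` per scenario),
#'   `replicates` (if requested), `table` (headline layout), `config`,
#'   `rr`.
#' @export
#' @examples
#' sim <- rvp_simulate(default_calibration(seed = 3),
#'                     n_per_stratum = 500)
#' print(sim)
rvp_simulate <- function(config = default_calibration(),
                         scenarios = c("I", "II", "III"), rr = 0.83,
                         coeffs = score_coefficients(),
                         n_per_stratum = NULL, n_reps = 0) {
  scenarios <- match.arg(scenarios, SCENARIOS, several.ok = TRUE)
  pop <- score_population(generate_population(config, n_per_stratum),
                          coeffs)
  decisions <- lapply(scenarios, function(sc)
    apply_scenario(pop, sc, coeffs))
  names(decisions) <- scenarios
  impacts <- lapply(decisions, function(d) compute_impact(pop, d, rr))
  replicates <- if (n_reps >= 2) {
    lapply(scenarios, function(sc)
      replicate_impact(config, sc, rr, n_reps = n_reps,
                       n_per_stratum = n_per_stratum, coeffs = coeffs))
  }
  if (!is.null(replicates)) names(replicates) <- scenarios
  structure(list(population = pop, decisions = decisions,
                 impacts = impacts, replicates = replicates,
                 table = impact_table(impacts), config = config,
                 rr = rr),
            class = "rvp_sim")
}

#' @export
print.rvp_sim <- function(x, ...) {
  cat(sprintf(
    "Virtual-population policy simulation: %d individuals, scenarios %s\n",
    nrow(x$population), paste(names(x$impacts), collapse = ", ")))
  t <- x$table
  t$men_eligible_pct <- round(t$men_eligible_pct, 1)
  t$women_eligible_pct <- round(t$women_eligible_pct, 1)
  t$nes_over_nep <- round(t$nes_over_nep, 0)
  print(t, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rvp_sim <- function(object, ...) {
  pop <- object$population
  cat(sprintf("Population: %d individuals (seed %d)\n", nrow(pop),
              object$config$seed))
  cat(sprintf("Mean 10-year fatal-CVD risk: %.2f%% (men %.2f%%, women %.2f%%)\n",
              100 * mean(pop$total_risk),
              100 * mean(pop$total_risk[pop$sex == "M"]),
              100 * mean(pop$total_risk[pop$sex == "F"])))
  for (sc in names(object$impacts)) {
    tot <- as.data.frame(object$impacts[[sc]])
    tot <- tot[tot$stratum == "total", ]
    cat(sprintf(
      "Scenario %-3s eligible %5.1f%%  events prevented %8.1f  eligible per event prevented %6.1f\n",
      sc, 100 * tot$nes_over_n, tot$nep, tot$nes_over_nep))
  }
  invisible(object)
}

#' @export
plot.rvp_sim <- function(x, ...) {
  t <- x$table
  t <- t[t$age_class != "total", ]
  scens <- unique(t$scenario)
  m <- rbind(men = matrix(t$men_eligible_pct, nrow = length(scens),
                          byrow = TRUE),
             women = matrix(t$women_eligible_pct, nrow = length(scens),
                            byrow = TRUE))
  oldpar <- graphics::par(mfrow = c(1, length(scens)))
  on.exit(graphics::par(oldpar))
  for (i in seq_along(scens)) {
    h <- rbind(t$men_eligible_pct[t$scenario == scens[i]],
               t$women_eligible_pct[t$scenario == scens[i]])
    graphics::barplot(h, beside = TRUE, names.arg = AGE_CLASSES,
                      col = c("grey30", "grey70"),
                      ylab = "eligible (% of class)",
                      main = paste("Scenario", scens[i]),
                      legend.text = c("men", "women"), ...)
  }
  invisible(x)
}

#' Run the pipeline from a configuration and write its artifacts
#'
#' Executes generation, scoring, eligibility and impact stages and
#' writes the population CSV, the stacked decisions CSV, the headline
#' impact CSV, a replicate summary CSV, the comparison CSV (when a
#' survey table is supplied) and a JSON manifest recording the seed and
#' a hash of the configuration.
#'
#' @param config a [population_config()] or path to its YAML file.
#' @param outdir output directory, created if missing.
#' @param scenarios scenarios to run.
#' @param rr treatment relative risk.
#' @param n_reps replicate populations for the spread summary (0 to
#'   skip).
#' @param survey optional path to an observed-survey CSV.
#' @param coeffs_path optional path to a SCORE coefficient file.
#' @param n_per_stratum optional fixed stratum size.
#' @param seed optional seed overriding the configuration's.
#' @param quiet suppress per-stage messages.
#' @return Invisibly, the `rvp_sim` object with `manifest` attached.
#' @export
run_pipeline <- function(config, outdir, scenarios = c("I", "II", "III"),
                         rr = 0.83, n_reps = 0, survey = NULL,
                         coeffs_path = NULL, n_per_stratum = NULL,
                         seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_population_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  coeffs <- if (is.null(coeffs_path)) score_coefficients() else
    score_coefficients(coeffs_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  sim <- rvp_simulate(config, scenarios, rr, coeffs, n_per_stratum,
                      n_reps)
  say("generated and scored %d individuals (seed %d)",
      nrow(sim$population), config$seed)

  write_population_csv(sim$population, file.path(outdir, "population.csv"))
  write_decisions_csv(do.call(rbind, sim$decisions),
                      file.path(outdir, "decisions.csv"))
  utils::write.csv(sim$table, file.path(outdir, "impact.csv"),
                   row.names = FALSE)
  for (sc in names(sim$impacts)) {
    tot <- as.data.frame(sim$impacts[[sc]])
    say("scenario %s: %d eligible, %.1f events prevented", sc,
        tot$nes[tot$stratum == "total"],
        tot$nep[tot$stratum == "total"])
  }
  if (!is.null(sim$replicates)) {
    reps <- do.call(rbind, lapply(names(sim$replicates), function(sc)
      cbind(scenario = sc, sim$replicates[[sc]]$summary)))
    utils::write.csv(reps, file.path(outdir, "replicates.csv"),
                     row.names = FALSE)
  }
  comparison <- NULL
  if (!is.null(survey)) {
    obs <- read_survey_table(survey)
    sc <- if ("III" %in% names(sim$impacts)) "III" else
      names(sim$impacts)[1]
    comparison <- compare_populations(sim$population, obs,
                                      sim$impacts[[sc]])
    utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
    say("comparison written against survey table (%s)", survey)
  }
  cfg_file <- file.path(outdir, "config.yaml")
  write_population_config(config, cfg_file)
  manifest <- list(
    seed = config$seed, scenarios = scenarios, rr = rr,
    n_reps = n_reps,
    n_individuals = nrow(sim$population),
    config_sha = as.vector(tools::md5sum(cfg_file)),
    coefficients_version = coeffs$version,
    outputs = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  sim$comparison <- comparison
  sim$manifest <- manifest
  invisible(sim)
}
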