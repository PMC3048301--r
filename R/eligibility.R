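BP_CATEGORIES <- c("normal", "high_normal", "grade1", "grade2", "grade3")
SCENARIOS <- c("I", "II", "III")

#' Classify blood pressure into guideline bands
#'
#' Systolic bands: `<130` normal, `130-139` high normal, `140-159`
#' grade 1, `160-179` grade 2, `>=180` grade 3; diastolic bands `<85`,
#' `85-89`, `90-99`, `100-109`, `>=110`.  The final category is the
#' higher of the two band assignments, following the usual European
#' convention; the "optimal" band is absorbed into `normal`.
#'
#' @param sbp,dbp systolic and diastolic pressure in mm Hg; vectorised,
#'   must satisfy `sbp > dbp > 0`.
#' @return A factor with levels `normal < high_normal < grade1 <
#'   grade2 < grade3`.
#' @export
bp_category <- function(sbp, dbp) {
  if (any(!(sbp > dbp & dbp > 0)))
    stop("blood pressures must satisfy sbp > dbp > 0", call. = FALSE)
  s <- findInterval(sbp, c(130, 140, 160, 180)) + 1L
  d <- findInterval(dbp, c(85, 90, 100, 110)) + 1L
  factor(BP_CATEGORIES[pmax(s, d)], levels = BP_CATEGORIES,
         ordered = TRUE)
}

#' Treatment-eligibility scenarios
#'
#' Three historical/current rules for starting blood-pressure-lowering
#' drugs:
#' * Scenario I - the historical hypertension definition: systolic
#'   `>= 160` or diastolic `>= 95` mm Hg.
#' * Scenario II - the current hypertension definition: systolic
#'   `>= 140` or diastolic `>= 90` mm Hg.
#' * Scenario III - the ESC blood-pressure-grade by risk-category grid
#'   (see [treatment_grid()]): any cell other than "no" counts as
#'   eligible ("consider drugs" and "drugs if persists" included).
#'
#' @param individual data frame with columns `sbp`, `dbp` (vectorised).
#' @param risk_category for scenario III, the individual's risk category
#'   from [risk_category()].
#' @param grid for scenario III, a recommendation grid; default
#'   [treatment_grid()].
#' @return Logical vector of eligibility.
#' @export
eligible_scenario1 <- function(individual) {
  individual$sbp >= 160 | individual$dbp >= 95
}

#' @rdname eligible_scenario1
#' @export
eligible_scenario2 <- function(individual) {
  individual$sbp >= 140 | individual$dbp >= 90
}

#' @rdname eligible_scenario1
#' @export
eligible_scenario3 <- function(individual, risk_category,
                               grid = treatment_grid()) {
  bp <- bp_category(individual$sbp, individual$dbp)
  rc <- as.character(risk_category)
  grid[cbind(rc, as.character(bp))] != "no"
}

#' The guideline recommendation grid
#'
#' The 4 risk-category x 5 blood-pressure-band grid of drug
#' recommendations used by scenario III.  Cells take values `"no"`,
#' `"consider"` or `"drugs_if_persists"` / `"drugs"`; anything other
#' than `"no"` makes the individual eligible.  The default reproduces
#' the 2007 European prevention-guideline pattern: grades 2-3 at any
#' risk, grade 1 from moderate risk upward, high-normal pressure from
#' increased risk upward, never at normal pressure.
#'
#' @param overrides optional named list of cells to replace, names as
#'   `"<risk>.<bp>"`, e.g. `list(low.grade1 = "consider")`.
#' @return A 4x5 character matrix, rows `low`, `moderate`, `increased`,
#'   `markedly_increased`; columns `normal`, `high_normal`, `grade1`,
#'   `grade2`, `grade3`.
#' @export
treatment_grid <- function(overrides = NULL) {
  g <- matrix(
    c("no", "no", "no",       "drugs_if_persists", "drugs",
      "no", "no", "consider", "drugs_if_persists", "drugs",
      "no", "consider", "drugs", "drugs", "drugs",
      "no", "consider", "drugs", "drugs", "drugs"),
    nrow = 4, byrow = TRUE,
    dimnames = list(RISK_CATEGORIES, BP_CATEGORIES))
  for (nm in names(overrides)) {
    key <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(key) != 2L || !key[1] %in% RISK_CATEGORIES ||
        !key[2] %in% BP_CATEGORIES)
      stop("unknown grid cell: ", nm, call. = FALSE)
    g[key[1], key[2]] <- match.arg(
      overrides[[nm]], c("no", "consider", "drugs", "drugs_if_persists"))
  }
  g
}

#' Apply an eligibility scenario to a population
#'
#' @param pop a scored population ([score_population()]) or, for
#'   scenarios I/II, any population data frame.
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param coeffs SCORE coefficients, used to score `pop` on the fly if
#'   scenario III is requested and `pop` carries no `total_risk`.
#' @param grid recommendation grid for scenario III.
#' @return A data frame of eligibility decisions with columns `id`,
#'   `scenario`, `eligible`, `bp_category`, `risk_category`.
#' @export
apply_scenario <- function(pop, scenario, coeffs = score_coefficients(),
                           grid = treatment_grid()) {
  if (!scenario %in% SCENARIOS)
    stop("unknown scenario: ", scenario, call. = FALSE)
  pop <- as.data.frame(pop)
  if (nrow(pop) == 0L)
    return(data.frame(id = integer(), scenario = character(),
                      eligible = logical(), bp_category = character(),
                      risk_category = character()))
  if (is.null(pop$total_risk)) pop <- score_population(pop, coeffs)
  eligible <- switch(scenario,
    I = eligible_scenario1(pop),
    II = eligible_scenario2(pop),
    III = eligible_scenario3(pop, pop$risk_category, grid))
  data.frame(id = pop$id, scenario = scenario, eligible = eligible,
             bp_category = as.character(bp_category(pop$sbp, pop$dbp)),
             risk_category = as.character(pop$risk_category))
}

#' Write eligibility decisions as CSV
#'
#' Columns `id,scenario,eligible,bp_category,risk_category` with
#' `eligible` coded `0`/`1`.
#'
#' @param decisions output of [apply_scenario()] (rows of several
#'   scenarios may be stacked).
#' @param path file path.
#' @export
write_decisions_csv <- function(decisions, path) {
  d <- decisions
  d$eligible <- as.integer(d$eligible)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
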