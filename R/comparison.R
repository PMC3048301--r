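#' Per-stratum hypertension prevalence
#'
#' Proportion with systolic `>= 140` or diastolic `>= 90` mm Hg — the
#' same predicate as eligibility scenario II, so the prevalence equals
#' that scenario's eligible share by construction.
#'
#' @param pop a population data frame.
#' @return Data frame with columns `stratum`, `n`, `prevalence`
#'   (one row per age-sex stratum).
#' @export
hypertension_prevalence <- function(pop) {
  pop <- as.data.frame(pop)
  if (nrow(pop) == 0L) stop("empty population", call. = FALSE)
  labs <- paste(pop$sex, pop$age_class)
  ht <- eligible_scenario2(pop)
  do.call(rbind, lapply(sort(unique(labs)), function(lab) {
    i <- labs == lab
    data.frame(stratum = lab, n = sum(i), prevalence = mean(ht[i]))
  }))
}

#' Reconstitute prevalence for an untreated virtual population
#'
#' The virtual population contains untreated individuals only, so its
#' hypertension prevalence understates the population value.  Treating
#' every treated survey participant as hypertensive, the reconstituted
#' prevalence is `t + (1 - t) * p`, where `t` is the treated fraction of
#' the stratum and `p` the untreated-population prevalence.
#'
#' @param p_rvp untreated-population prevalence in `[0, 1]`.
#' @param treated_fraction treated share of the stratum in `[0, 1]`.
#' @return Reconstituted prevalence; equals `p_rvp` at `t = 0` and 1 at
#'   `t = 1`, monotone in both arguments.
#' @export
reconstitute_prevalence <- function(p_rvp, treated_fraction) {
  if (any(p_rvp < 0 | p_rvp > 1 | treated_fraction < 0 |
          treated_fraction > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  treated_fraction + (1 - treated_fraction) * p_rvp
}

#' Read an observed-survey table
#'
#' Expects columns `sex, age_class, prevalence, pct_treated,
#' pct_known_untreated, pct_unknown`, all proportions of the whole
#' stratum; the three components must sum to the prevalence.  The table
#' shipped under `extdata/survey_synthetic.csv` is an illustrative
#' synthetic example, not survey data.
#'
#' @param path CSV path.
#' @return Validated data frame with a `stratum` column added.
#' @export
read_survey_table <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_class", "prevalence", "pct_treated",
            "pct_known_untreated", "pct_unknown")
  if (!all(need %in% names(obs)))
    stop("survey table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  gap <- abs(obs$pct_treated + obs$pct_known_untreated + obs$pct_unknown -
               obs$prevalence)
  if (any(gap > 1e-6))
    stop("treated + known-untreated + unknown must equal the prevalence",
         call. = FALSE)
  if (any(unlist(obs[, need[-(1:2)]]) < 0 |
          unlist(obs[, need[-(1:2)]]) > 1))
    stop("survey proportions must lie in [0, 1]", call. = FALSE)
  obs$stratum <- paste(obs$sex, obs$age_class)
  obs
}

#' Treated-over-eligible ratio per stratum
#'
#' Divides the observed treated share of each stratum by the simulated
#' eligible share; a ratio above 1 flags over-treatment relative to the
#' guideline simulation, below 1 under-treatment.  Strata where nobody
#' is eligible get `NA` with `undefined = TRUE`.
#'
#' @param observation survey table from [read_survey_table()].
#' @param impact an `rvp_impact` from [compute_impact()] (scenario III
#'   for guideline comparisons).
#' @return Data frame with `stratum`, `pct_treated`,
#'   `eligible_pct_of_stratum`, `ratio`, `undefined`.
#' @export
treated_over_eligible <- function(observation, impact) {
  imp <- as.data.frame(impact)
  imp <- imp[imp$stratum != "total", ]
  if (!setequal(observation$stratum, imp$stratum))
    stop("survey and impact strata do not match", call. = FALSE)
  m <- match(imp$stratum, observation$stratum)
  elig <- imp$nes_over_n
  ratio <- ifelse(elig > 0, observation$pct_treated[m] / elig, NA_real_)
  data.frame(stratum = imp$stratum,
             pct_treated = observation$pct_treated[m],
             eligible_pct_of_stratum = elig,
             ratio = ratio, undefined = !(elig > 0))
}

#' Compare simulated and observed hypertension burden
#'
#' Assembles, per stratum, the untreated virtual-population prevalence,
#' its reconstituted value given the observed treated fractions, the
#' observed prevalence, the simulated eligible share and the
#' treated-over-eligible ratio.
#'
#' @param pop a scored population.
#' @param observation survey table from [read_survey_table()].
#' @param impact an `rvp_impact` for the scenario to compare against.
#' @return Data frame with one row per stratum, all six strata present.
#' @export
compare_populations <- function(pop, observation, impact) {
  prev <- hypertension_prevalence(pop)
  toe <- treated_over_eligible(observation, impact)
  m <- match(prev$stratum, observation$stratum)
  if (anyNA(m)) stop("survey table missing strata: ",
                     paste(prev$stratum[is.na(m)], collapse = ", "),
                     call. = FALSE)
  data.frame(stratum = prev$stratum,
             rvp_initial_prevalence = prev$prevalence,
             reconstituted_prevalence =
               reconstitute_prevalence(prev$prevalence,
                                       observation$pct_treated[m]),
             observed_prevalence = observation$prevalence[m],
             eligible_pct_of_stratum =
               toe$eligible_pct_of_stratum[match(prev$stratum,
                                                 toe$stratum)],
             treated_over_eligible_ratio =
               toe$ratio[match(prev$stratum, toe$stratum)])
}
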