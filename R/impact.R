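#' Expected number of fatal events
#'
#' The expected event count is the sum of individual 10-year risks, with
#' each treated individual's risk multiplied by the treatment relative
#' risk.  It is an exact expectation, not a sampled count.
#'
#' @param risks individual 10-year risks in `[0, 1]`.
#' @param treated logical vector of the same length.
#' @param rr treatment relative risk in `(0, 1]` (default 0.83).
#' @return The expected event count.
#' @export
expected_events <- function(risks, treated, rr = 0.83) {
  if (length(risks) != length(treated))
    stop("risks and treated mask differ in length", call. = FALSE)
  if (any(risks < 0 | risks > 1)) stop("risks must lie in [0, 1]",
                                       call. = FALSE)
  if (rr <= 0 || rr > 1) stop("relative risk must lie in (0, 1]",
                              call. = FALSE)
  sum(risks * ifelse(treated, rr, 1))
}

impact_row <- function(risks, eligible, rr) {
  ne_baseline <- sum(risks)
  ne_t <- expected_events(risks, eligible, rr)
  nes <- sum(eligible)
  nep <- ne_baseline - ne_t
  data.frame(n = length(risks), nes = nes, ne_baseline = ne_baseline,
             ne_t = ne_t, nep = nep,
             nes_over_n = if (length(risks)) nes / length(risks) else NA_real_,
             nes_over_nep = if (nep > 0) nes / nep else NA_real_)
}

#' Public-health impact of an eligibility scenario
#'
#' For each age-sex stratum and overall: the number of eligible subjects
#' (NES), the expected events without treatment (`ne_baseline`), under
#' treatment of all eligible subjects (`ne_t`), the events prevented
#' (`nep = ne_baseline - ne_t`) and the efficiency ratio `nes_over_nep`
#' (eligible subjects per event prevented; smaller is more efficient).
#' When no events are prevented the ratio is reported as `NA` rather
#' than dividing by zero.
#'
#' @param pop a scored population ([score_population()]).
#' @param decisions eligibility decisions from [apply_scenario()] for
#'   one scenario, covering the population.
#' @param rr treatment relative risk (default 0.83).
#' @return An object of class `rvp_impact`: a data frame with one row
#'   per stratum plus a `total` row.
#' @export
compute_impact <- function(pop, decisions, rr = 0.83) {
  pop <- as.data.frame(pop)
  if (is.null(pop$total_risk))
    stop("population must be scored first (see score_population)",
         call. = FALSE)
  if (length(unique(decisions$scenario)) > 1L)
    stop("decisions must belong to a single scenario", call. = FALSE)
  eligible <- decisions$eligible[match(pop$id, decisions$id)]
  if (anyNA(eligible))
    stop("decisions do not cover the population", call. = FALSE)
  labs <- paste(pop$sex, pop$age_class)
  rows <- lapply(sort(unique(labs)), function(lab) {
    i <- labs == lab
    cbind(stratum = lab, impact_row(pop$total_risk[i], eligible[i], rr))
  })
  out <- rbind(do.call(rbind, rows),
               cbind(stratum = "total",
                     impact_row(pop$total_risk, eligible, rr)))
  structure(out, class = c("rvp_impact", "data.frame"),
            scenario = unique(decisions$scenario), rr = rr)
}

#' @export
print.rvp_impact <- function(x, digits = 3, ...) {
  cat(sprintf("Impact of scenario %s (relative risk %.2f)\n",
              attr(x, "scenario"), attr(x, "rr")))
  d <- as.data.frame(x)
  d$nes_over_n <- round(100 * d$nes_over_n, 1)
  names(d)[names(d) == "nes_over_n"] <- "eligible_pct"
  print(format(d, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Replicate-population distribution of impact measures
#'
#' Regenerates the virtual population `n_reps` times under child seeds
#' derived from `seed`, recomputes NES and NEP for the scenario each
#' time, and reports the median and inter-quartile range over
#' replicates.
#'
#' @param config a [population_config()].
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param rr treatment relative risk.
#' @param n_reps number of replicate populations (`>= 2`).
#' @param seed master seed for the replicate series; defaults to the
#'   configuration seed.
#' @param n_per_stratum optional fixed stratum size passed to
#'   [generate_population()].
#' @param coeffs SCORE coefficients.
#' @return An object of class `rvp_replicates`: a list with the
#'   per-replicate table and a summary of median and quartiles for
#'   `nes` and `nep`.
#' @export
replicate_impact <- function(config, scenario, rr = 0.83, n_reps = 20,
                             seed = config$seed, n_per_stratum = NULL,
                             coeffs = score_coefficients()) {
  if (n_reps < 2) stop("n_reps must be at least 2", call. = FALSE)
  reps <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- child_seed(seed, 1000L + r)
    pop <- score_population(generate_population(cfg, n_per_stratum),
                            coeffs)
    dec <- apply_scenario(pop, scenario, coeffs)
    imp <- as.data.frame(compute_impact(pop, dec, rr))
    tot <- imp[imp$stratum == "total", ]
    data.frame(rep = r, nes = tot$nes, nep = tot$nep,
               ne_baseline = tot$ne_baseline)
  })
  tab <- do.call(rbind, reps)
  summ <- do.call(rbind, lapply(c("nes", "nep", "ne_baseline"),
    function(v) {
      q <- stats::quantile(tab[[v]], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(measure = v, q1 = q[1], median = q[2], q3 = q[3])
    }))
  structure(list(replicates = tab, summary = summ, scenario = scenario,
                 n_reps = n_reps, seed = seed),
            class = "rvp_replicates")
}

#' @export
print.rvp_replicates <- function(x, ...) {
  cat(sprintf("Scenario %s over %d replicate populations (seed %d)\n",
              x$scenario, x$n_reps, x$seed))
  print(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.rvp_replicates <- function(x, ...) {
  tab <- x$replicates
  graphics::boxplot(list(NEP = tab$nep),
                    ylab = "expected events prevented",
                    main = sprintf("Scenario %s: NEP over %d replicates",
                                   x$scenario, x$n_reps), ...)
  invisible(x)
}

#' Bernoulli simulation of event counts
#'
#' Draws each individual's fatal event as an independent Bernoulli trial
#' with probability equal to the (treated-adjusted) risk, and returns the
#' simulated event counts.  This sampling view exists as an internal
#' check of the expectation formula in [expected_events()] and as an
#' optional output; the headline impact numbers are exact expectations.
#'
#' @inheritParams expected_events
#' @param n_reps number of simulation replicates.
#' @param seed integer seed.
#' @return Integer vector of `n_reps` simulated event counts.
#' @export
simulate_event_counts <- function(risks, treated, rr = 0.83,
                                  n_reps = 1000, seed = 1L) {
  p <- risks * ifelse(treated, rr, 1)
  set.seed(seed)
  vapply(seq_len(n_reps),
         function(r) sum(stats::rbinom(length(p), 1L, p)), integer(1))
}

#' Tabulate impact across scenarios in the headline layout
#'
#' @param impacts named list of `rvp_impact` objects (names are scenario
#'   ids).
#' @return Data frame with one row per scenario x age class: percent
#'   eligible among men and women, and the scenario's total
#'   eligible-per-event-prevented ratio on the `total` rows.
#' @export
impact_table <- function(impacts) {
  rows <- lapply(names(impacts), function(sc) {
    d <- as.data.frame(impacts[[sc]])
    cls <- c(AGE_CLASSES, "total")
    do.call(rbind, lapply(cls, function(cl) {
      if (cl == "total") {
        men <- d[d$stratum %in% paste("M", AGE_CLASSES), ]
        wom <- d[d$stratum %in% paste("F", AGE_CLASSES), ]
        data.frame(scenario = sc, age_class = "total",
                   men_eligible_pct = 100 * sum(men$nes) / sum(men$n),
                   women_eligible_pct = 100 * sum(wom$nes) / sum(wom$n),
                   nes_over_nep = d$nes_over_nep[d$stratum == "total"])
      } else {
        data.frame(scenario = sc, age_class = cl,
                   men_eligible_pct =
                     100 * d$nes_over_n[d$stratum == paste("M", cl)],
                   women_eligible_pct =
                     100 * d$nes_over_n[d$stratum == paste("F", cl)],
                   nes_over_nep = NA_real_)
      }
    }))
  })
  do.call(rbind, rows)
}
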