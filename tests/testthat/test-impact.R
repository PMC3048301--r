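coeffs <- score_coefficients()

scored_pop <- function(seed = 31L, n = 300) {
  score_population(generate_population(tiny_config(seed = seed),
                                       n_per_stratum = n), coeffs)
}

test_that("expected events are risk sums scaled by treatment", {
  expect_equal(expected_events(c(0.1, 0.2), c(FALSE, FALSE)), 0.3)
  expect_equal(expected_events(c(0.1, 0.2), c(TRUE, TRUE), rr = 0.83),
               0.249)
  # null treatment effect leaves the expectation unchanged
  r <- runif(50)
  m <- runif(50) > 0.5
  expect_equal(expected_events(r, m, rr = 1), sum(r))
  expect_error(expected_events(c(0.1), c(TRUE, FALSE)), "length")
  expect_error(expected_events(c(1.4), TRUE), "\\[0, 1\\]")
})

test_that("impact summaries follow the closed forms", {
  # one eligible individual with risk 0.05 under RR 0.83:
  # NEP = 0.05 * 0.17, ratio = 1 / (0.05 * 0.17)
  pop <- structure(
    data.frame(id = 1:2, sex = "M", age_class = "45-54", age = 50,
               sbp = c(170, 120), dbp = c(80, 70), tchol = 6,
               smoker = 0L, diabetic = 0L,
               total_risk = c(0.05, 0.0)),
    class = c("rvp_population", "data.frame"))
  dec <- data.frame(id = 1:2, scenario = "I",
                    eligible = c(TRUE, FALSE))
  imp <- as.data.frame(compute_impact(pop, dec, rr = 0.83))
  tot <- imp[imp$stratum == "total", ]
  expect_equal(tot$nes, 1)
  expect_equal(tot$nep, 0.0085, tolerance = 1e-12)
  expect_equal(tot$nes_over_nep, 1 / 0.0085, tolerance = 1e-12)

  # nobody eligible: zero prevented, ratio undefined (NA, no div by 0)
  dec0 <- data.frame(id = 1:2, scenario = "I", eligible = FALSE)
  tot0 <- as.data.frame(compute_impact(pop, dec0))
  tot0 <- tot0[tot0$stratum == "total", ]
  expect_equal(tot0$nes, 0)
  expect_equal(tot0$nep, 0)
  expect_true(is.na(tot0$nes_over_nep))
})

test_that("treated-subset event ratio equals the configured relative risk", {
  pop <- scored_pop()
  for (sc in c("I", "II", "III")) {
    dec <- apply_scenario(pop, sc, coeffs)
    el <- dec$eligible[match(pop$id, dec$id)]
    if (!any(el)) next
    ne_t <- expected_events(pop$total_risk[el], rep(TRUE, sum(el)),
                            rr = 0.83)
    ne_b <- sum(pop$total_risk[el])
    expect_equal(ne_t / ne_b, 0.83, tolerance = 1e-12)
  }
})

test_that("events prevented scale linearly in one minus the relative risk", {
  pop <- scored_pop(seed = 8L)
  dec <- apply_scenario(pop, "II", coeffs)
  nep_at <- function(rr) {
    d <- as.data.frame(compute_impact(pop, dec, rr))
    d$nep[d$stratum == "total"]
  }
  # halving (1 - RR) halves NEP exactly
  expect_equal(nep_at(1 - 0.17 / 2), nep_at(0.83) / 2,
               tolerance = 1e-12)
  expect_equal(nep_at(1), 0)
})

test_that("stratum rows are consistent with the overall totals", {
  pop <- scored_pop(seed = 13L)
  dec <- apply_scenario(pop, "III", coeffs)
  imp <- as.data.frame(compute_impact(pop, dec))
  strat <- imp[imp$stratum != "total", ]
  tot <- imp[imp$stratum == "total", ]
  expect_equal(sum(strat$n), tot$n)
  expect_equal(sum(strat$nes), tot$nes)
  expect_equal(sum(strat$nep), tot$nep, tolerance = 1e-12)
  # overall proportion is the size-weighted mean of stratum proportions
  expect_equal(sum(strat$nes_over_n * strat$n) / tot$n, tot$nes_over_n,
               tolerance = 1e-12)
  expect_true(all(strat$nep >= 0))
  expect_true(all(strat$ne_t <= strat$ne_baseline))
  expect_true(all(strat$nes <= strat$n))
})

test_that("decision coverage and scenario mixing are rejected", {
  pop <- scored_pop(seed = 3L, n = 20)
  dec <- apply_scenario(pop, "I", coeffs)
  expect_error(compute_impact(pop, dec[-1, ]), "cover")
  mixed <- rbind(dec, transform(dec, scenario = "II"))
  expect_error(compute_impact(pop, mixed), "single scenario")
})

test_that("replicate impacts are reproducible with coherent quartiles", {
  cfg <- tiny_config(seed = 55L)
  a <- replicate_impact(cfg, "II", n_reps = 6, n_per_stratum = 150,
                        coeffs = coeffs)
  b <- replicate_impact(cfg, "II", n_reps = 6, n_per_stratum = 150,
                        coeffs = coeffs)
  expect_identical(a$replicates, b$replicates)
  expect_true(all(a$summary$q1 <= a$summary$median &
                    a$summary$median <= a$summary$q3))
  expect_error(replicate_impact(cfg, "II", n_reps = 1), "at least 2")
  # distinct replicate populations actually vary
  expect_gt(stats::sd(a$replicates$nep), 0)
})

test_that("median replicate events prevented track the expectation", {
  cfg <- tiny_config(seed = 19L)
  reps <- replicate_impact(cfg, "II", n_reps = 30, n_per_stratum = 400,
                           coeffs = coeffs)
  neps <- reps$replicates$nep
  single <- rvp_simulate(cfg, scenarios = "II", n_per_stratum = 400,
                         coeffs = coeffs)
  ref <- as.data.frame(single$impacts$II)
  ref <- ref$nep[ref$stratum == "total"]
  se <- stats::sd(neps) / sqrt(length(neps))
  expect_lt(abs(median(neps) - ref), max(3 * se, 0.05 * ref))
})

test_that("Bernoulli event draws agree with the exact expectation", {
  pop <- scored_pop(seed = 23L, n = 500)
  dec <- apply_scenario(pop, "II", coeffs)
  el <- dec$eligible[match(pop$id, dec$id)]
  counts <- simulate_event_counts(pop$total_risk, el, rr = 0.83,
                                  n_reps = 400, seed = 99L)
  exp_ev <- expected_events(pop$total_risk, el, rr = 0.83)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - exp_ev), 3 * se)
})

test_that("the headline table carries per-class percentages and ratios", {
  sim <- rvp_simulate(tiny_config(seed = 2L), n_per_stratum = 250,
                      coeffs = coeffs)
  t <- sim$table
  expect_equal(nrow(t), 12L)  # 3 scenarios x (3 classes + total)
  expect_true(all(is.na(t$nes_over_nep[t$age_class != "total"])))
  tot <- t[t$age_class == "total", ]
  for (i in seq_len(nrow(tot))) {
    imp <- as.data.frame(sim$impacts[[tot$scenario[i]]])
    expect_equal(tot$nes_over_nep[i],
                 imp$nes_over_nep[imp$stratum == "total"])
  }
})
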