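test_that("stratum and configuration invariants are enforced", {
  cfg <- default_calibration()
  expect_length(cfg$strata, 6L)
  expect_setequal(vapply(cfg$strata, `[[`, "", "sex"), c("M", "F"))
  w <- sum(vapply(cfg$strata, `[[`, 0, "weight"))
  expect_equal(w, 1, tolerance = 1e-12)

  bad <- cfg$strata[[1]]
  bad$mean[["age"]] <- 50  # outside 35-44
  expect_error(rvpsim:::validate_stratum_spec(bad), "outside age class")

  asym <- cfg$strata[[1]]
  asym$covariance[1, 2] <- asym$covariance[2, 1] + 5
  expect_error(rvpsim:::validate_stratum_spec(asym), "symmetric")

  npd <- cfg$strata[[1]]
  npd$covariance <- matrix(c(1, 2, 0, 0,
                             2, 1, 0, 0,
                             0, 0, 1, 0,
                             0, 0, 0, 1), 4, 4)
  expect_error(rvpsim:::validate_stratum_spec(npd), "positive semi-definite")

  cfg$strata[[1]]$weight <- cfg$strata[[1]]$weight + 0.1
  expect_error(population_config(cfg$strata), "sum to 1")
})

test_that("generation is seeded, stratified and respects invariants", {
  cfg <- tiny_config(seed = 11L)
  pop <- generate_population(cfg, n_per_stratum = 400)
  expect_equal(nrow(pop), 6L * 400L)
  expect_equal(unname(table(paste(pop$sex, pop$age_class))),
               rep(400L, 6L), ignore_attr = TRUE)

  # every individual satisfies the physiological and age-class bounds
  expect_true(all(pop$age >= 35 & pop$age < 65))
  expect_true(all(pop$sbp > pop$dbp))
  expect_true(all(pop$sbp >= 70 & pop$sbp <= 260))
  expect_true(all(pop$tchol > 0))
  for (lab in unique(paste(pop$sex, pop$age_class))) {
    cls <- sub("^[MF] ", "", lab)
    lohi <- switch(cls, "35-44" = c(35, 45), "45-54" = c(45, 55),
                   "55-64" = c(55, 65))
    a <- pop$age[paste(pop$sex, pop$age_class) == lab]
    expect_true(all(a >= lohi[1] & a < lohi[2]))
  }

  # bit-identical regeneration under the same seed
  pop2 <- generate_population(tiny_config(seed = 11L),
                              n_per_stratum = 400)
  expect_identical(as.data.frame(pop), as.data.frame(pop2))
  pop3 <- generate_population(tiny_config(seed = 12L),
                              n_per_stratum = 400)
  expect_false(identical(pop$sbp, pop3$sbp))
})

test_that("stratum draws do not depend on stratum order", {
  cfg <- tiny_config(seed = 5L)
  rev_cfg <- population_config(rev(unname(cfg$strata)),
                               sample_fraction = cfg$sample_fraction,
                               seed = cfg$seed)
  a <- generate_population(cfg, n_per_stratum = 150)
  b <- generate_population(rev_cfg, n_per_stratum = 150)
  key <- function(p) {
    d <- as.data.frame(p)[order(p$sex, p$age_class, p$age, p$sbp), ]
    d$id <- NULL
    rownames(d) <- NULL
    d
  }
  expect_equal(key(a), key(b))
})

test_that("zero draws and stratum-size rounding behave as specified", {
  cfg <- tiny_config()
  for (i in seq_along(cfg$strata)) cfg$strata[[i]]$size <- 3L
  cfg$sample_fraction <- 0.01  # 0.03 per stratum -> rounds to 0
  empty <- generate_population(cfg)
  expect_equal(nrow(empty), 0L)
  expect_error(summarize_population(empty), "empty")

  # round-half-away-from-zero on size * fraction: 0.5 -> 1
  for (i in seq_along(cfg$strata)) cfg$strata[[i]]$size <- 50L
  one <- generate_population(cfg)  # 0.5 each
  expect_equal(nrow(one), 6L)
})

test_that("degenerate calibrations are rejected with the stratum named", {
  cfg <- tiny_config()
  cfg$strata[[1]]$mean[["age"]] <- 44.9
  cfg$strata[[1]]$covariance["age", "age"] <- 100  # most draws leave class
  expect_error(generate_population(cfg, n_per_stratum = 500),
               "rejection rate.*50%|degenerate calibration")
  expect_error(generate_population(cfg, n_per_stratum = 500),
               "M 35-44")
})

test_that("summaries recover the moments of what was drawn", {
  pop <- generate_population(tiny_config(seed = 2L), n_per_stratum = 300)
  s <- summarize_population(pop)
  expect_length(s$strata, 6L)
  lab <- "M 45-54"
  d <- as.data.frame(pop)[paste(pop$sex, pop$age_class) == lab, ]
  expect_equal(s$strata[[lab]]$mean[["sbp"]], mean(d$sbp))
  expect_equal(s$strata[[lab]]$covariance["sbp", "dbp"],
               cov(d$sbp, d$dbp))
  expect_equal(s$strata[[lab]]$smoking_prevalence, mean(d$smoker))
  # determinism: summarizing twice gives identical tables
  expect_identical(s$table, summarize_population(pop)$table)

  single <- pop[3, ]
  s1 <- summarize_population(single)
  expect_equal(s1$strata[[1]]$mean[["sbp"]], single$sbp)
  expect_true(all(s1$strata[[1]]$covariance == 0))
})

test_that("latent-Gaussian binary mode honours requested correlations", {
  cfg <- tiny_config(seed = 9L)
  bc <- matrix(0, 2, 4)
  bc[1, 2] <- 0.5  # smoker latent correlated with sbp
  cfg$binary_mode <- "latent"
  cfg$binary_correlation <- bc
  pop <- generate_population(cfg, n_per_stratum = 20000)
  d <- as.data.frame(pop)[pop$sex == "M" & pop$age_class == "35-44", ]
  # smokers should have visibly higher mean sbp under the latent link
  expect_gt(mean(d$sbp[d$smoker == 1]), mean(d$sbp[d$smoker == 0]) + 3)
  expect_equal(mean(d$smoker), 0.35, tolerance = 0.03)
})

test_that("configuration YAML and population CSV round-trip", {
  cfg <- default_calibration(seed = 77L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_population_config(cfg, path)
  cfg2 <- read_population_config(path)
  expect_equal(cfg2$sample_fraction, cfg$sample_fraction)
  expect_equal(cfg2$seed, cfg$seed)
  for (lab in names(cfg$strata)) {
    expect_equal(cfg2$strata[[lab]]$mean, cfg$strata[[lab]]$mean)
    expect_equal(cfg2$strata[[lab]]$covariance,
                 cfg$strata[[lab]]$covariance)
  }
  # identical populations from the round-tripped configuration
  expect_identical(
    as.data.frame(generate_population(cfg, n_per_stratum = 50)),
    as.data.frame(generate_population(cfg2, n_per_stratum = 50)))

  pop <- generate_population(cfg, n_per_stratum = 40)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(pop, csv)
  back <- read_population_csv(csv)
  expect_equal(back$sbp, pop$sbp, tolerance = 1e-12)
  expect_identical(names(back),
                   c("id", "sex", "age_class", "age", "sbp", "dbp",
                     "tchol", "smoker", "diabetic"))
})
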