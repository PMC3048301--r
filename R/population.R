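# Deterministic child seed for a stratum or replicate, tied to the
# stratum identity (not list order) so strata are order-independent.
child_seed <- function(master, key) {
  idx <- if (is.character(key)) {
    canonical <- as.vector(outer(SEXES, AGE_CLASSES, stratum_label))
    match(key, canonical)
  } else {
    as.integer(key)
  }
  if (anyNA(idx)) stop("unknown seed key: ", key, call. = FALSE)
  as.integer((as.numeric(master) + 104729 * idx) %% 2147483647)
}

round_half_away <- function(x) trunc(x + sign(x) * 0.5)

# Draw n individuals for one stratum by rejection sampling: draws whose
# age falls outside the class interval, or with sbp <= dbp, sbp outside
# [70, 260] or tchol <= 0, are discarded and redrawn.  Clipping is never
# used: it would pile mass on the thresholds that drive eligibility.
draw_stratum <- function(spec, n, seed, binary_mode = "independent",
                         binary_correlation = NULL) {
  bounds <- age_class_bounds(spec$age_class)
  set.seed(seed)
  kept <- NULL
  drawn <- 0L
  latent <- binary_mode == "latent"
  while (is.null(kept) || nrow(kept) < n) {
    batch <- max(1000L, ceiling(1.3 * (n - if (is.null(kept)) 0L else nrow(kept))))
    if (latent) {
      bc <- binary_correlation
      if (is.null(bc)) bc <- matrix(0, 2, 4)
      sd <- sqrt(diag(spec$covariance))
      cor6 <- diag(6)
      cor6[1:4, 1:4] <- stats::cov2cor(spec$covariance)
      cor6[5:6, 1:4] <- bc
      cor6[1:4, 5:6] <- t(bc)
      sigma6 <- diag(c(sd, 1, 1)) %*% cor6 %*% diag(c(sd, 1, 1))
      x <- MASS::mvrnorm(batch, mu = c(spec$mean, 0, 0), Sigma = sigma6)
      z <- x[, 5:6, drop = FALSE]
      x <- x[, 1:4, drop = FALSE]
      smoker <- as.integer(z[, 1] > stats::qnorm(1 - spec$smoking_prevalence))
      diabetic <- as.integer(z[, 2] > stats::qnorm(1 - spec$diabetes_prevalence))
    } else {
      x <- MASS::mvrnorm(batch, mu = spec$mean, Sigma = spec$covariance)
      if (batch == 1L) x <- matrix(x, nrow = 1)
      smoker <- stats::rbinom(batch, 1L, spec$smoking_prevalence)
      diabetic <- stats::rbinom(batch, 1L, spec$diabetes_prevalence)
    }
    colnames(x) <- RISK_FACTORS
    ok <- x[, "age"] >= bounds[1] & x[, "age"] < bounds[2] &
      x[, "sbp"] > x[, "dbp"] & x[, "sbp"] >= 70 & x[, "sbp"] <= 260 &
      x[, "tchol"] > 0
    drawn <- drawn + batch
    acc <- cbind(as.data.frame(x[ok, , drop = FALSE]),
                 smoker = smoker[ok], diabetic = diabetic[ok])
    kept <- if (is.null(kept)) acc else rbind(kept, acc)
    if (nrow(kept) < drawn / 2)
      stop("degenerate calibration for stratum ",
           stratum_label(spec$sex, spec$age_class),
           ": rejection rate exceeds 50%", call. = FALSE)
  }
  kept <- kept[seq_len(n), , drop = FALSE]
  data.frame(sex = spec$sex, age_class = spec$age_class, kept,
             stringsAsFactors = FALSE)
}

#' Generate a virtual population
#'
#' Draws a stratified sample of virtual individuals.  Per stratum,
#' `round(size * sample_fraction)` individuals (half away from zero) are
#' drawn from the stratum's multivariate normal; draws outside the age
#' class or physiologically impossible (systolic below diastolic,
#' systolic outside 70-260 mm Hg, non-positive cholesterol) are rejected
#' and redrawn.  Smoking and diabetes are Bernoulli draws at the stratum
#' prevalence (or latent-Gaussian thresholds, see
#' [population_config()]).  The result is bit-reproducible given the
#' configuration seed.
#'
#' @param config a [population_config()].
#' @param n_per_stratum optional integer overriding the
#'   `size * sample_fraction` rule with a fixed count per stratum.
#' @return A data frame of class `rvp_population` with columns
#'   `id`, `sex`, `age_class`, `age`, `sbp`, `dbp`, `tchol`, `smoker`,
#'   `diabetic`.
#' @export
#' @examples
#' pop <- generate_population(default_calibration(seed = 7),
#'                            n_per_stratum = 200)
#' table(pop$sex, pop$age_class)
generate_population <- function(config, n_per_stratum = NULL) {
  stopifnot(inherits(config, "population_config"))
  parts <- lapply(names(config$strata), function(lab) {
    spec <- config$strata[[lab]]
    n <- if (is.null(n_per_stratum)) {
      round_half_away(spec$size * config$sample_fraction)
    } else {
      as.integer(n_per_stratum)
    }
    if (n <= 0L) return(NULL)
    draw_stratum(spec, n, seed = child_seed(config$seed, lab),
                 binary_mode = config$binary_mode,
                 binary_correlation = config$binary_correlation)
  })
  pop <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(pop))
    pop <- data.frame(sex = character(), age_class = character(),
                      age = numeric(), sbp = numeric(), dbp = numeric(),
                      tchol = numeric(), smoker = integer(),
                      diabetic = integer())
  pop <- cbind(id = seq_len(nrow(pop)), pop)
  structure(pop, class = c("rvp_population", "data.frame"),
            seed = config$seed)
}

#' @export
print.rvp_population <- function(x, ...) {
  cat(sprintf("Virtual population: %d individuals, %d strata\n",
              nrow(x), length(unique(paste(x$sex, x$age_class)))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Per-stratum empirical moments of a population
#'
#' @param pop a population from [generate_population()].
#' @return A list with one element per stratum, each holding `n`, the
#'   empirical `mean` and `covariance` of the continuous risk factors and
#'   the `smoking_prevalence` / `diabetes_prevalence`; plus a `table`
#'   data-frame summary.
#' @export
summarize_population <- function(pop) {
  if (nrow(pop) == 0L) stop("cannot summarize an empty population",
                            call. = FALSE)
  labs <- paste(pop$sex, pop$age_class)
  strata <- lapply(split(as.data.frame(pop), labs), function(d) {
    x <- as.matrix(d[, RISK_FACTORS])
    list(n = nrow(d),
         mean = colMeans(x),
         covariance = if (nrow(d) > 1L) stats::cov(x) else
           matrix(0, 4, 4, dimnames = list(RISK_FACTORS, RISK_FACTORS)),
         smoking_prevalence = mean(d$smoker),
         diabetes_prevalence = mean(d$diabetic))
  })
  tab <- do.call(rbind, lapply(names(strata), function(lab) {
    s <- strata[[lab]]
    data.frame(stratum = lab, n = s$n, t(s$mean),
               smoker = s$smoking_prevalence,
               diabetic = s$diabetes_prevalence)
  }))
  list(strata = strata, table = tab[order(tab$stratum), ])
}

#' Write or read a population CSV
#'
#' Columns `id,sex,age_class,age,sbp,dbp,tchol,smoker,diabetic`; sex is
#' coded `M`/`F`, booleans as `0`/`1`.
#'
#' @param pop a population data frame.
#' @param path file path.
#' @export
write_population_csv <- function(pop, path) {
  utils::write.csv(as.data.frame(pop)[, c("id", "sex", "age_class", "age",
                                          "sbp", "dbp", "tchol", "smoker",
                                          "diabetic")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(pop, class = c("rvp_population", "data.frame"))
}
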