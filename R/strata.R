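RISK_FACTORS <- c("age", "sbp", "dbp", "tchol")
AGE_CLASSES <- c("35-44", "45-54", "55-64")
SEXES <- c("M", "F")

age_class_bounds <- function(age_class) {
  switch(age_class,
    "35-44" = c(35, 45),
    "45-54" = c(45, 55),
    "55-64" = c(55, 65),
    stop("unknown age class: ", age_class, call. = FALSE)
  )
}

#' Define one age-sex stratum of the virtual population
#'
#' A stratum is one cell of the 2 sexes x 3 ten-year age classes design.
#' Its continuous risk factors (age in years, systolic and diastolic blood
#' pressure in mm Hg, total cholesterol in mmol/L) follow a multivariate
#' normal distribution with the given mean vector and covariance matrix;
#' smoking and diabetes are binary covariates with stratum-specific
#' prevalences.
#'
#' @param sex `"M"` or `"F"`.
#' @param age_class one of `"35-44"`, `"45-54"`, `"55-64"`; individuals are
#'   drawn on the half-open interval `[lower, upper)` in years.
#' @param mean named numeric vector of length 4 with entries
#'   `age`, `sbp`, `dbp`, `tchol`.
#' @param covariance symmetric positive-definite 4x4 matrix in matching
#'   units, dimnames as `mean`.
#' @param smoking_prevalence,diabetes_prevalence proportions in `[0, 1]`.
#' @param weight this stratum's share of the reference population; the six
#'   shares must sum to 1.
#' @param size reference population head count for the stratum.
#' @return An object of class `stratum_spec`.
#' @export
stratum_spec <- function(sex, age_class, mean, covariance,
                         smoking_prevalence, diabetes_prevalence,
                         weight, size) {
  sex <- match.arg(sex, SEXES)
  age_class <- match.arg(age_class, AGE_CLASSES)
  mean <- unlist(mean)[RISK_FACTORS]
  covariance <- as.matrix(covariance)
  dimnames(covariance) <- list(RISK_FACTORS, RISK_FACTORS)
  spec <- structure(
    list(sex = sex, age_class = age_class, mean = mean,
         covariance = covariance,
         smoking_prevalence = smoking_prevalence,
         diabetes_prevalence = diabetes_prevalence,
         weight = weight, size = size),
    class = "stratum_spec")
  validate_stratum_spec(spec)
  spec
}

validate_stratum_spec <- function(spec) {
  with(spec, {
    if (anyNA(mean) || length(mean) != 4L)
      stop("stratum mean must be a named 4-vector (age, sbp, dbp, tchol)",
           call. = FALSE)
    if (!isSymmetric(unname(covariance), tol = 1e-8))
      stop("covariance matrix must be symmetric", call. = FALSE)
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("covariance matrix must be positive semi-definite", call. = FALSE)
    bounds <- age_class_bounds(age_class)
    if (mean[["age"]] < bounds[1] || mean[["age"]] >= bounds[2])
      stop("mean age ", mean[["age"]], " lies outside age class ",
           age_class, call. = FALSE)
    for (p in c(smoking_prevalence, diabetes_prevalence, weight))
      if (!is.finite(p) || p < 0 || p > 1)
        stop("prevalences and weight must lie in [0, 1]", call. = FALSE)
    if (!is.finite(size) || size < 0)
      stop("stratum size must be a non-negative count", call. = FALSE)
  })
  invisible(spec)
}

stratum_label <- function(sex, age_class) paste(sex, age_class, sep = " ")

#' Assemble a population configuration
#'
#' @param strata list of [stratum_spec()] objects, one per age-sex cell.
#' @param sample_fraction fraction of the reference population to draw
#'   (default 0.04, i.e. a 4\% sample).
#' @param seed master integer seed; per-stratum child seeds are derived
#'   from it deterministically, so stratum order does not affect draws.
#' @param binary_mode `"independent"` draws smoking and diabetes as
#'   independent Bernoulli variables at the stratum prevalence;
#'   `"latent"` thresholds two extra standard-normal coordinates that may
#'   be correlated with the continuous block via `binary_correlation`.
#' @param binary_correlation optional 2x4 matrix of latent correlations
#'   (rows smoker, diabetic; columns age, sbp, dbp, tchol), used only in
#'   `"latent"` mode.  Default zero.
#' @return An object of class `population_config`.
#' @export
population_config <- function(strata, sample_fraction = 0.04, seed = 1L,
                              binary_mode = c("independent", "latent"),
                              binary_correlation = NULL) {
  binary_mode <- match.arg(binary_mode)
  if (!is.finite(sample_fraction) || sample_fraction <= 0 ||
      sample_fraction > 1)
    stop("sample_fraction must lie in (0, 1]", call. = FALSE)
  lapply(strata, validate_stratum_spec)
  labels <- vapply(strata, function(s) stratum_label(s$sex, s$age_class), "")
  if (anyDuplicated(labels))
    stop("duplicate stratum: ", labels[duplicated(labels)][1], call. = FALSE)
  w <- sum(vapply(strata, `[[`, 0, "weight"))
  if (abs(w - 1) > 1e-9)
    stop("stratum weights must sum to 1 (got ", format(w), ")", call. = FALSE)
  names(strata) <- labels
  structure(
    list(strata = strata, sample_fraction = sample_fraction,
         seed = as.integer(seed), binary_mode = binary_mode,
         binary_correlation = binary_correlation),
    class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat("Virtual population configuration\n")
  cat(sprintf("  strata: %d, sample fraction: %g, seed: %d, binaries: %s\n",
              length(x$strata), x$sample_fraction, x$seed, x$binary_mode))
  for (s in x$strata)
    cat(sprintf(
      "  %s %s  n_ref=%-9d mean SBP/DBP %5.1f/%5.1f  chol %4.2f  smk %4.2f dia %4.2f w %5.3f\n",
      s$sex, s$age_class, s$size, s$mean[["sbp"]], s$mean[["dbp"]],
      s$mean[["tchol"]], s$smoking_prevalence, s$diabetes_prevalence,
      s$weight))
  invisible(x)
}

cov_from_sd_cor <- function(sd, cor) {
  v <- diag(sd) %*% cor %*% diag(sd)
  dimnames(v) <- list(RISK_FACTORS, RISK_FACTORS)
  v
}

# Common within-stratum correlation structure of the default calibration.
default_cor <- function() {
  cor <- diag(4)
  dimnames(cor) <- list(RISK_FACTORS, RISK_FACTORS)
  cor["age", "sbp"] <- cor["sbp", "age"] <- 0.25
  cor["age", "dbp"] <- cor["dbp", "age"] <- 0.22
  cor["age", "tchol"] <- cor["tchol", "age"] <- 0.22
  cor["sbp", "dbp"] <- cor["dbp", "sbp"] <- 0.70
  cor["sbp", "tchol"] <- cor["tchol", "sbp"] <- 0.25
  cor["dbp", "tchol"] <- cor["tchol", "dbp"] <- 0.22
  cor
}

#' Shipped default calibration of the virtual population
#'
#' Returns a fully specified [population_config()] with French-plausible
#' risk-factor distributions for untreated 35-64 year-olds: mean blood
#' pressure and cholesterol rise across age classes and are higher in men,
#' systolic and diastolic pressure are strongly positively correlated, and
#' smoking declines while diabetes rises with age.  The numbers are a
#' documented approximation chosen to reproduce the qualitative structure
#' of French population surveys of the late 1990s; they are not estimates
#' from any survey microdata.
#'
#' Ages are drawn tightly around each class midpoint (SD 1.2 years), so
#' the age gradient of risk is carried by the class means rather than by
#' within-class dispersion; this keeps the rejection step (which truncates
#' age to the class interval) from distorting the configured moments.
#'
#' @param seed master seed stored in the configuration.
#' @param sample_fraction fraction of the reference population to draw.
#' @return A `population_config` with six strata.
#' @export
default_calibration <- function(seed = 1L, sample_fraction = 0.04) {
  cor <- default_cor()
  # means: age, sbp (mm Hg), dbp (mm Hg), tchol (mmol/L); sds likewise
  rows <- list(
    list("M", "35-44", c(39.5, 127, 80, 5.6), c(1.2, 15, 10, 0.95),
         smk = 0.35, dia = 0.02, w = 0.175, size = 4270000L),
    list("M", "45-54", c(49.5, 132, 84, 5.9), c(1.2, 16, 10, 1.00),
         smk = 0.30, dia = 0.05, w = 0.170, size = 4148000L),
    list("M", "55-64", c(59.5, 138, 86, 6.0), c(1.2, 17, 10, 1.00),
         smk = 0.22, dia = 0.09, w = 0.150, size = 3660000L),
    list("F", "35-44", c(39.5, 118, 75, 5.4), c(1.2, 14, 9, 0.90),
         smk = 0.28, dia = 0.01, w = 0.175, size = 4270000L),
    list("F", "45-54", c(49.5, 126, 79, 5.8), c(1.2, 16, 10, 0.95),
         smk = 0.22, dia = 0.03, w = 0.175, size = 4270000L),
    list("F", "55-64", c(59.5, 136, 82, 6.3), c(1.2, 18, 10, 1.00),
         smk = 0.12, dia = 0.06, w = 0.155, size = 3782000L))
  strata <- lapply(rows, function(r) {
    mu <- r[[3]]; names(mu) <- RISK_FACTORS
    stratum_spec(sex = r[[1]], age_class = r[[2]], mean = mu,
                 covariance = cov_from_sd_cor(r[[4]], cor),
                 smoking_prevalence = r$smk, diabetes_prevalence = r$dia,
                 weight = r$w, size = r$size)
  })
  population_config(strata, sample_fraction = sample_fraction, seed = seed)
}

#' Read or write a population configuration as YAML
#'
#' The schema has top-level keys `sample_fraction`, `seed`, `binary_mode`
#' and a `strata` list whose elements carry `sex`, `age_class`, `mean`
#' (mapping of age/sbp/dbp/tchol), `covariance` (4x4 row list),
#' `smoking_prevalence`, `diabetes_prevalence`, `weight` and `size`.
#'
#' @param config a `population_config`.
#' @param path file path.
#' @return `read_population_config()` returns a `population_config`;
#'   `write_population_config()` returns `path` invisibly.
#' @export
write_population_config <- function(config, path) {
  strata <- lapply(unname(config$strata), function(s) {
    list(sex = s$sex, age_class = s$age_class,
         mean = as.list(s$mean),
         covariance = apply(s$covariance, 1, as.list, simplify = FALSE),
         smoking_prevalence = s$smoking_prevalence,
         diabetes_prevalence = s$diabetes_prevalence,
         weight = s$weight, size = s$size)
  })
  yaml::write_yaml(
    list(sample_fraction = config$sample_fraction, seed = config$seed,
         binary_mode = config$binary_mode, strata = strata),
    path, precision = 17)
  invisible(path)
}

#' @rdname write_population_config
#' @export
read_population_config <- function(path) {
  raw <- yaml::read_yaml(path)
  strata <- lapply(raw$strata, function(s) {
    mu <- unlist(s$mean)[RISK_FACTORS]
    cv <- do.call(rbind, lapply(s$covariance, unlist))
    stratum_spec(sex = s$sex, age_class = s$age_class, mean = mu,
                 covariance = cv,
                 smoking_prevalence = s$smoking_prevalence,
                 diabetes_prevalence = s$diabetes_prevalence,
                 weight = s$weight, size = s$size)
  })
  population_config(strata,
                    sample_fraction = raw$sample_fraction,
                    seed = raw$seed %||% 1L,
                    binary_mode = raw$binary_mode %||% "independent")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
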