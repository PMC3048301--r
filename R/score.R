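ENDPOINTS <- c("chd", "non_chd")
RISK_CATEGORIES <- c("low", "moderate", "increased", "markedly_increased")

#' Load SCORE risk-equation coefficients
#'
#' Reads a coefficient file holding, per endpoint (coronary heart disease
#' and non-coronary cardiovascular disease) and sex, the Weibull
#' baseline-survival parameters (`alpha`, `p`) and the log-hazard-ratio
#' coefficients for smoking, systolic blood pressure (per mm Hg above
#' 120) and total cholesterol (per mmol/L above 6), plus sex-specific
#' diabetes risk multipliers.  The shipped default is the published
#' low-risk-region calibration; the file's `version` tag allows other
#' calibrations to be swapped in.
#'
#' @param path YAML coefficient file; default is the file shipped with
#'   the package.
#' @return An object of class `score_coefficients`.
#' @export
score_coefficients <- function(path = system.file("extdata",
                                                  "score_coefficients.yaml",
                                                  package = "rvpsim")) {
  raw <- yaml::read_yaml(path)
  for (e in ENDPOINTS) {
    for (s in SEXES) {
      b <- raw$endpoints[[e]][[s]]
      if (is.null(b)) stop("coefficient block missing: ", e, "/", s,
                           call. = FALSE)
      if (b$p <= 0) stop("Weibull shape p must be positive", call. = FALSE)
    }
  }
  if (raw$horizon <= 0) stop("horizon must be positive", call. = FALSE)
  if (any(unlist(raw$diabetes_multiplier) < 1))
    stop("diabetes multipliers must be >= 1", call. = FALSE)
  structure(raw, class = "score_coefficients")
}

#' @export
print.score_coefficients <- function(x, ...) {
  cat(sprintf("SCORE coefficients [%s], horizon %d y\n", x$version,
              x$horizon))
  for (e in ENDPOINTS) for (s in SEXES) {
    b <- x$endpoints[[e]][[s]]
    cat(sprintf("  %-8s %s: alpha=%6.1f p=%4.2f  betas smoker=%.2f sbp=%.3f tchol=%.2f\n",
                e, s, b$alpha, b$p, b$beta_smoker, b$beta_sbp, b$beta_tchol))
  }
  invisible(x)
}

#' Weibull baseline survival to a given age
#'
#' `S0(age) = exp(-exp(alpha) * (age - 20)^p)`: the probability that a
#' person free of the endpoint at age 20 with reference covariates
#' survives the endpoint to `age`.
#'
#' @param age age in years, `>= 20`; vectorised.
#' @param endpoint `"chd"` or `"non_chd"`.
#' @param sex `"M"` or `"F"`.
#' @param coeffs a [score_coefficients()] object.
#' @return Survival probabilities in `(0, 1]`, non-increasing in age.
#' @export
baseline_survival <- function(age, endpoint, sex, coeffs) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  sex <- match.arg(sex, SEXES)
  if (any(age < 20)) stop("baseline survival is defined for ages >= 20",
                          call. = FALSE)
  b <- coeffs$endpoints[[endpoint]][[sex]]
  exp(-exp(b$alpha) * (age - 20)^b$p)
}

score_linear_predictor <- function(sbp, tchol, smoker, endpoint, sex,
                                   coeffs) {
  b <- coeffs$endpoints[[endpoint]][[sex]]
  b$beta_smoker * smoker +
    b$beta_sbp * (sbp - coeffs$reference$sbp) +
    b$beta_tchol * (tchol - coeffs$reference$tchol)
}

#' Ten-year risk of one fatal endpoint
#'
#' Cause-specific risk over `[age, age + 10]`:
#' `1 - (S0(age + 10) / S0(age))^exp(w)` with individual log-hazard
#' `w = beta_smoker * smoker + beta_sbp * (sbp - 120)
#'    + beta_tchol * (tchol - 6)`.
#'
#' @param individual a data frame (or one-row list) with columns `sex`,
#'   `age`, `sbp`, `tchol`, `smoker`; vectorised over rows of a single
#'   sex.
#' @inheritParams baseline_survival
#' @return Probabilities in `[0, 1]`.
#' @export
ten_year_cause_risk <- function(individual, endpoint, coeffs) {
  sex <- unique(individual$sex)
  if (length(sex) != 1L)
    stop("ten_year_cause_risk expects rows of a single sex", call. = FALSE)
  age <- individual$age
  if (any(age < 20) || any(age + coeffs$horizon > 100))
    stop("age + horizon outside the coefficients' validity range",
         call. = FALSE)
  s_now <- baseline_survival(age, endpoint, sex, coeffs)
  s_then <- baseline_survival(age + coeffs$horizon, endpoint, sex, coeffs)
  w <- score_linear_predictor(individual$sbp, individual$tchol,
                              individual$smoker, endpoint, sex, coeffs)
  pmin(1, pmax(0, 1 - (s_then / s_now)^exp(w)))
}

#' Total ten-year fatal cardiovascular risk
#'
#' Computes the coronary and non-coronary fatal risks separately, sums
#' them, multiplies the sum by the sex-specific diabetes multiplier for
#' diabetic individuals, and caps at 1.
#'
#' @param individual data frame with columns `sex`, `age`, `sbp`,
#'   `tchol`, `smoker`, `diabetic` (rows may mix sexes).
#' @param coeffs a [score_coefficients()] object.
#' @return A data frame with columns `chd_risk`, `nonchd_risk`,
#'   `total_risk`.
#' @export
total_cvd_risk <- function(individual, coeffs) {
  individual <- as.data.frame(individual)
  n <- nrow(individual)
  chd <- nonchd <- numeric(n)
  for (s in SEXES) {
    i <- individual$sex == s
    if (!any(i)) next
    chd[i] <- ten_year_cause_risk(individual[i, , drop = FALSE], "chd",
                                  coeffs)
    nonchd[i] <- ten_year_cause_risk(individual[i, , drop = FALSE],
                                     "non_chd", coeffs)
  }
  mult <- ifelse(individual$diabetic == 1L,
                 unlist(coeffs$diabetes_multiplier)[individual$sex], 1)
  data.frame(chd_risk = chd, nonchd_risk = nonchd,
             total_risk = pmin(1, (chd + nonchd) * mult))
}

#' Score a whole population
#'
#' @param pop a population from [generate_population()].
#' @inheritParams total_cvd_risk
#' @return `pop` with columns `chd_risk`, `nonchd_risk`, `total_risk`
#'   and `risk_category` appended.
#' @export
score_population <- function(pop, coeffs = score_coefficients()) {
  risks <- total_cvd_risk(pop, coeffs)
  out <- cbind(as.data.frame(pop), risks,
               risk_category = risk_category(risks$total_risk))
  structure(out, class = c("rvp_population", "data.frame"))
}

#' Bin a total risk into the guideline risk categories
#'
#' Contiguous half-open bins: `low` below 1\%, `moderate` 1-5\%,
#' `increased` 5-10\%, `markedly_increased` at or above 10\%.
#'
#' @param total_risk probabilities in `[0, 1]`; vectorised.
#' @return A factor with levels `low < moderate < increased <
#'   markedly_increased`.
#' @export
risk_category <- function(total_risk) {
  if (any(!is.finite(total_risk)) || any(total_risk < 0) ||
      any(total_risk > 1))
    stop("total_risk must lie in [0, 1]", call. = FALSE)
  cut(total_risk, breaks = c(-Inf, 0.01, 0.05, 0.10, Inf),
      labels = RISK_CATEGORIES, right = FALSE, ordered_result = TRUE)
}
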