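# Small configurations and fixture individuals used across the suite.

# A two-parameter toy configuration: same correlation structure as the
# shipped calibration but only as large as a test needs.
tiny_config <- function(seed = 42L, zero_covariance = FALSE) {
  cfg <- default_calibration(seed = seed)
  if (zero_covariance) {
    for (i in seq_along(cfg$strata)) {
      v <- cfg$strata[[i]]$covariance
      cfg$strata[[i]]$covariance <- diag(diag(v))
      dimnames(cfg$strata[[i]]$covariance) <- dimnames(v)
    }
  }
  cfg
}

# One synthetic individual per cell of the risk-category x BP-band grid.
# SBP values pick each band via the systolic rule (DBP kept low).
grid_individuals <- function() {
  bp_levels <- c(normal = 120, high_normal = 135, grade1 = 150,
                 grade2 = 170, grade3 = 190)
  risk_levels <- c(low = 0.005, moderate = 0.03, increased = 0.07,
                   markedly_increased = 0.15)
  cells <- expand.grid(risk = names(risk_levels), bp = names(bp_levels),
                       stringsAsFactors = FALSE)
  data.frame(id = seq_len(nrow(cells)),
             risk = cells$risk, bp = cells$bp,
             sbp = bp_levels[cells$bp],
             dbp = 70,
             total_risk = risk_levels[cells$risk],
             row.names = NULL)
}

# Population of identical normotensive, low-risk individuals.
normotensive_population <- function(n = 50) {
  structure(
    data.frame(id = seq_len(n), sex = rep(c("M", "F"), length.out = n),
               age_class = "35-44", age = 40, sbp = 120, dbp = 70,
               tchol = 5, smoker = 0L, diabetic = 0L),
    class = c("rvp_population", "data.frame"))
}
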