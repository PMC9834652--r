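# Shared fixtures and independent oracles for the test suite.

# Packaged reference dataset, loaded once.
study <- wheat_bran_study()

# Wheat bran chemistry + determined energy values (6 samples), the basis of
# the correlation and regression checks.
bran_data <- local({
  m <- merge(study$ingredients, study$ingredient_energy, by = "ingredient_id")
  m[grepl("bran", m$ingredient_id), ]
})

# Independent normal-equations oracle for least squares.
ols_oracle <- function(data, response, predictors) {
  X <- cbind(1, as.matrix(data[predictors]))
  y <- data[[response]]
  beta <- solve(t(X) %*% X, t(X) %*% y)
  stats::setNames(drop(beta), c("(Intercept)", predictors))
}

# Brute-force Pearson correlation via covariance sums.
cor_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# A minimal two-diet formulation (basal + one 30% test diet) built in code,
# with every ingredient at the same DM so that the as-fed and DM inclusion
# bases coincide and difference-method round trips are exact.
make_toy_diets <- function(ge_basal = 17.0, ge_test_diet = 17.5,
                           cp_basal = 18, cp_test = 18, dm = 88) {
  inc <- rbind(
    data.frame(diet_id = "BASAL",
               ingredient_id = c("corn", "soybean_meal", "minerals"),
               inclusion_pct_asfed = c(75, 22, 3),
               is_mixture_component = c(TRUE, TRUE, FALSE),
               is_test_ingredient = FALSE),
    data.frame(diet_id = "TEST",
               ingredient_id = c("corn", "soybean_meal", "test_ing", "minerals"),
               inclusion_pct_asfed = c(52.35, 14.65, 30, 3),
               is_mixture_component = c(TRUE, TRUE, FALSE, FALSE),
               is_test_ingredient = c(FALSE, FALSE, TRUE, FALSE)))
  chem <- data.frame(diet_id = c("BASAL", "TEST"),
                     GE = c(ge_basal, ge_test_diet), DM = dm,
                     CP = c(cp_basal, cp_test), EE = 2.2,
                     NDF = c(13, 21), ADF = c(4.2, 6.4), ash = 5.5)
  structure(list(inclusions = inc, chemistry = chem), class = "diet_table")
}

# Ingredient table matching make_toy_diets(): only the test ingredient needs
# measured GE and DM for the difference method.
make_toy_ingredients <- function(ge_test = 19.0, dm = 88) {
  validate_ingredients(data.frame(
    ingredient_id = "test_ing", GE = ge_test, DM = dm, CP = 17, EE = 2.1,
    starch = 15, NDF = 43, ADF = 11, IDF = 40, SDF = 4, TDF = 44, ash = 5.6))
}
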