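test_that("Noblet equations reproduce the reference predictions", {
  ie <- study$ingredient_energy
  b <- bran_data
  ne1 <- noblet_ne1(b$DE, b$EE, b$starch, b$CP, b$ADF)
  ne2 <- noblet_ne2(b$ME, b$EE, b$starch, b$CP, b$ADF)
  expect_equal(ne1, b$predicted_NE1, tolerance = 0.01)
  expect_equal(ne2, b$predicted_NE2, tolerance = 0.01)
  expect_equal(noblet_ne1(10, 0, 0, 0, 0), 7.00)
  expect_equal(noblet_ne2(10, 0, 0, 0, 0), 7.26)
  # affine in each argument: doubling DE with zero chemistry doubles NE1
  expect_equal(noblet_ne1(20, 0, 0, 0, 0), 2 * noblet_ne1(10, 0, 0, 0, 0))
  v <- noblet_validation(ie, study$ingredients)
  expect_equal(v$predicted_NE1[v$ingredient_id == "wheat_bran_1"], 6.71,
               tolerance = 5e-3)
})

test_that("relative error compares determined NE with the mean prediction", {
  expect_equal(relative_error(12.47, 10.56, 10.35), 19.3, tolerance = 0.05)
  expect_equal(relative_error(10, 9, 11), 0)
  b3 <- bran_data[bran_data$ingredient_id == "wheat_bran_3", ]
  expect_equal(relative_error(8.15,
                              noblet_ne1(b3$DE, b3$EE, b3$starch, b3$CP, b3$ADF),
                              noblet_ne2(b3$ME, b3$EE, b3$starch, b3$CP, b3$ADF)),
               -7.4, tolerance = 0.05)
  # invariant to common rescaling
  expect_equal(relative_error(3 * 12.47, 3 * 10.56, 3 * 10.35),
               relative_error(12.47, 10.56, 10.35))
  expect_error(relative_error(10, -4, 4), "positive")
})

test_that("Pearson matrix matches the covariance oracle and is well-formed", {
  cm <- pearson_matrix(bran_data, c("GE", "CP", "NDF", "starch", "DE", "ME", "NE"))
  expect_equal(cm$n, 6)
  expect_equal(diag(cm$r), rep(1, 7), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1))
  for (pair in list(c("NE", "CP"), c("NDF", "starch"), c("NE", "NDF")))
    expect_equal(cm$r[pair[1], pair[2]],
                 cor_oracle(bran_data[[pair[1]]], bran_data[[pair[2]]]),
                 tolerance = 1e-12)
  expect_equal(cm$r["NE", "CP"], 0.92, tolerance = 0.01)
  expect_equal(cm$r["NDF", "starch"], -0.94, tolerance = 0.01)
  # p-values agree with cor.test's t transform
  ct <- cor.test(bran_data$NE, bran_data$CP)
  expect_equal(cm$p["NE", "CP"], ct$p.value)
  expect_lt(cm$p["NE", "CP"], 0.01)

  cz <- bran_data; cz$GE <- 19
  expect_warning(out <- pearson_matrix(cz, c("GE", "CP")), "zero-variance")
  expect_true(is.na(out$r["GE", "CP"]))
  expect_error(pearson_matrix(bran_data[1:2, ], c("CP", "NE")), "at least 3")
})

test_that("least squares agrees with the normal-equations oracle", {
  cases <- list("CP", "NDF", "ADF", "ME", c("GE", "CP"), c("GE", "ME"))
  for (pred in cases) {
    m <- ols_fit(bran_data, "NE", pred)
    expect_equal(m$coefficients, ols_oracle(bran_data, "NE", pred),
                 tolerance = 1e-9, info = paste(pred, collapse = "+"))
  }
  # exact line y = 2x + 1
  d <- data.frame(x = 1:6, y = 2 * (1:6) + 1)
  m <- ols_fit(d, "y", "x")
  expect_equal(unname(m$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(m$r.squared, 1)
  # RMSE convention sqrt(SSE/(n - p - 1)) and information criteria
  m2 <- ols_fit(bran_data, "NE", "CP")
  fit <- lm(NE ~ CP, bran_data)
  sse <- sum(residuals(fit)^2)
  expect_equal(m2$rmse, sqrt(sse / 4))
  expect_equal(m2$aic, 6 * log(sse / 6) + 2 * 2)
  expect_equal(m2$bic, 6 * log(sse / 6) + 2 * log(6))
  # rank deficiency is a named error
  dd <- bran_data; dd$CP2 <- 2 * dd$CP
  expect_error(ols_fit(dd, "NE", c("CP", "CP2")), "collinear")
  expect_error(ols_fit(bran_data[1:3, ], "NE", c("GE", "CP")),
               "more observations")
})

test_that("single-predictor R2 equals the squared correlation", {
  for (v in c("CP", "NDF", "ADF", "GE", "ME"))
    expect_equal(ols_fit(bran_data, "NE", v)$r.squared,
                 cor(bran_data$NE, bran_data[[v]])^2, tolerance = 1e-12)
})

test_that("reference prediction equations are reproduced", {
  m_cp <- ols_fit(bran_data, "NE", "CP")
  expect_equal(unname(m_cp$coefficients), c(-0.80, 0.46), tolerance = 0.01)
  expect_equal(m_cp$r.squared, 0.85, tolerance = 0.01)
  m_gecp <- ols_fit(bran_data, "NE", c("GE", "CP"))
  expect_equal(unname(m_gecp$coefficients), c(-21.65, 1.20, 0.35),
               tolerance = 0.01)
  expect_equal(m_gecp$r.squared, 0.94, tolerance = 0.01)
  expect_equal(ols_fit(bran_data, "NE", "NDF")$r.squared, 0.71,
               tolerance = 0.01)
})

test_that("stepwise selection is deterministic and respects its thresholds", {
  chem_pool <- c("GE", "CP", "EE", "starch", "NDF", "ADF", "ash")
  mods <- stepwise_select(bran_data, "NE", chem_pool)
  expect_gt(length(mods), 0)
  first_single <- Filter(function(m) length(m$predictors) == 1, mods)[[1]]
  expect_equal(first_single$predictors, "CP")  # CP is the first predictor

  # {GE, ME}: the two-variable model tops the ranking at the default levels
  mods2 <- stepwise_select(bran_data, "NE", c("GE", "ME"))
  expect_setequal(mods2[[1]]$predictors, c("GE", "ME"))
  expect_equal(mods2[[1]]$r.squared, 0.94, tolerance = 0.01)

  # at strict 0.05 entry no second predictor can clear the bar on n = 6
  mods3 <- stepwise_select(bran_data, "NE", c("GE", "ME"),
                           entry_alpha = 0.05, stay_alpha = 0.05)
  expect_equal(mods3[[1]]$predictors, "ME")
  expect_true(all(lengths(lapply(mods3, `[[`, "predictors")) == 1))

  # deterministic: identical inputs give identical rankings
  rerun <- stepwise_select(bran_data, "NE", chem_pool)
  expect_identical(lapply(mods, `[[`, "predictors"),
                   lapply(rerun, `[[`, "predictors"))

  # a candidate perfectly collinear with the response: one model, R2 = 1
  d <- bran_data; d$NEcopy <- d$NE
  mods4 <- stepwise_select(d, "NE", "NEcopy")
  expect_equal(mods4[[1]]$r.squared, 1)

  # nothing passes entry -> empty list with a diagnostic
  noise <- data.frame(y = c(1, 5, 2, 4, 3, 6), x = c(3, 3.1, 3, 2.9, 3, 3.1))
  expect_message(out <- stepwise_select(noise, "y", "x", entry_alpha = 0.01),
                 "no candidate")
  expect_length(out, 0)
})

test_that("severe collinearity blocks entry", {
  set.seed(1)
  d <- bran_data
  d$NDF2 <- d$NDF + rnorm(6, 0, 1e-4)  # VIF far beyond 10 with NDF
  mods <- stepwise_select(d, "NE", c("NDF", "NDF2"), entry_alpha = 0.5,
                          stay_alpha = 0.5, collinearity_limit = 10)
  expect_true(all(lengths(lapply(mods, `[[`, "predictors")) == 1))
})
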