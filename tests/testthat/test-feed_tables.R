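test_that("packaged ingredient table reads and validates", {
  ing <- study$ingredients
  expect_s3_class(ing, "ingredient_table")
  expect_equal(nrow(ing), 7)
  expect_equal(ing$NDF[ing$ingredient_id == "wheat_bran_1"], 51.01)
  expect_equal(ing$starch[ing$ingredient_id == "wheat_shorts"], 31.85)
})

test_that("reading handles empty files, missing columns and derived fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste0("ingredient_id,GE_MJ_kgDM,DM_pct,CP_pctDM,EE_pctDM,",
                "starch_pctDM,NDF_pctDM,ADF_pctDM,IDF_pctDM,SDF_pctDM,",
                "TDF_pctDM,ash_pctDM")
  writeLines(hdr, path)
  expect_equal(nrow(read_ingredient_table(path)), 0)

  # SDF absent -> derived as TDF - IDF
  writeLines(c(sub(",SDF_pctDM", "", hdr),
               "x,18.72,87.95,17.32,2.13,12.81,51.01,14.47,46.88,50.45,6.66"),
             path)
  expect_equal(read_ingredient_table(path)$SDF, 3.57)

  writeLines(c("ingredient_id,GE_MJ_kgDM", "x,18.7"), path)
  expect_error(read_ingredient_table(path), "DM_pct")
  expect_error(read_ingredient_table("no/such/file.csv"), "not found")
})

test_that("ingredient invariants are enforced with row and rule named", {
  base <- study$ingredients[1, ]
  bad <- base; bad$ADF <- bad$NDF + 1
  expect_error(validate_ingredients(bad), "ADF exceeds NDF")
  bad <- base; bad$IDF <- bad$TDF + 0.5; bad$SDF <- NA
  expect_error(validate_ingredients(bad), "IDF exceeds TDF")
  bad <- base; bad$SDF <- bad$SDF + 1
  expect_error(validate_ingredients(bad), "SDF.*inconsistent")
  bad <- base; bad$CP <- 120
  expect_error(validate_ingredients(bad), "\\[0, 100\\]")
  bad <- base; bad$N <- 2
  expect_error(validate_ingredients(bad), "CP.*inconsistent")
  ok <- base; ok$N <- ok$CP / 6.25
  expect_silent(validate_ingredients(ok))
})

test_that("derived chemistry follows the subtraction and 6.25 N rules", {
  expect_equal(derive_sdf(21.49, 16.93), 4.56)
  expect_equal(derive_sdf(10, 10), 0)
  expect_equal(derive_sdf(50.45, 46.88), 3.57)
  expect_error(derive_sdf(10, 11), "IDF cannot exceed TDF")
  expect_equal(cp_from_nitrogen(0), 0)
  expect_equal(cp_from_nitrogen(2.9152), 18.22)
  expect_equal(cp_from_nitrogen(3.2), 20)
  expect_error(cp_from_nitrogen(-1), "nonnegative")
})

test_that("write/read round trip is the identity on validated records", {
  path <- withr::local_tempfile(fileext = ".csv")
  ing <- study$ingredients
  ing$N <- ing$CP / 6.25
  write_ingredient_table(ing, path)
  back <- read_ingredient_table(path)
  for (col in setdiff(names(ing), "ingredient_id"))
    expect_equal(signif(back[[col]], 6), signif(ing[[col]], 6), info = col)
})

test_that("composition summary matches direct sd computation", {
  brans <- study$ingredients[1:6, ]
  s <- summarize_compositions(brans, c("CP", "NDF", "starch"))
  expect_equal(s$mean[s$analyte == "CP"], 18.20, tolerance = 5e-3)
  cp <- brans$CP
  expect_equal(s$cv[s$analyte == "CP"],
               100 * sqrt(mean((cp - mean(cp))^2)) / mean(cp))
  expect_equal(round(s$cv[s$analyte == "CP"], 2), 5.98)
  s2 <- summarize_compositions(brans, "CP", cv_denominator = "sample")
  expect_equal(s2$cv, 100 * sd(cp) / mean(cp))

  # identical values -> CV 0; mean invariant to order; CV scale-invariant
  same <- brans; same$CP <- 18
  expect_equal(summarize_compositions(same, "CP")$cv, 0)
  shuf <- brans[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(summarize_compositions(shuf, "NDF")$mean,
               s$mean[s$analyte == "NDF"])
  scaled <- brans; scaled$NDF <- brans$NDF * 3.7
  expect_equal(summarize_compositions(scaled, "NDF")$cv,
               s$cv[s$analyte == "NDF"])
  expect_error(summarize_compositions(brans[1, ], "CP"), "at least 2")
})

test_that("diet table validates inclusions and mixture structure", {
  d <- study$diets
  expect_equal(length(unique(d$inclusions$diet_id)), 8)
  fr <- diet_mixture_fraction(d, "WB1")
  expect_equal(fr$f_mix, 0.6735)
  expect_equal(fr$f_test, 0.30)
  expect_equal(fr$test_id, "wheat_bran_1")
  expect_equal(diet_mixture_fraction(d, "BASAL")$f_mix, 0.9735)
  expect_true(is.na(diet_mixture_fraction(d, "BASAL")$test_id))

  bad <- make_toy_diets()
  bad$inclusions$inclusion_pct_asfed[1] <- 80
  tmp_inc <- withr::local_tempfile(fileext = ".csv")
  tmp_chem <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad$inclusions, tmp_inc, row.names = FALSE)
  chem <- bad$chemistry
  names(chem) <- c("diet_id", "GE_MJ_kgDM", "DM_pct", "CP_pctDM", "EE_pctDM",
                   "NDF_pctDM", "ADF_pctDM", "ash_pctDM")
  write.csv(chem, tmp_chem, row.names = FALSE)
  expect_error(read_diet_tables(tmp_inc, tmp_chem), "sum to")
})
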