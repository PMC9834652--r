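test_that("ATTD and nitrogen balance follow the intake-output arithmetic", {
  expect_equal(attd(100, 0), 100)
  expect_equal(attd(41.2, 5.4), 86.89, tolerance = 5e-4)
  expect_equal(attd(100, 20), 80)
  expect_warning(attd(10, 12), "exceeds intake")
  expect_error(attd(0, 1), "positive")

  expect_equal(nitrogen_balance(41.2, 5.4, 7.7), 28.1)
  expect_equal(nitrogen_balance(10, 10, 0), 0)
  expect_equal(nitrogen_balance(47.0, 11.6, 9.5), 25.9)
})

test_that("energy partition operations reproduce the reference diet values", {
  # DE: synthetic pig, true digestibility 0.88 on an 18.41 MJ/kg DM diet
  dmi <- 1.4
  expect_equal(diet_de(18.41e3 * dmi, 0.12 * 18.41e3 * dmi, dmi),
               16.2008, tolerance = 1e-6)
  expect_equal(diet_de(18.41e3 * dmi, 0, dmi), 18.41)
  expect_equal(diet_de(18.41e3 * dmi, 18.41e3 * dmi, dmi), 0)

  # ME: basal diet, 0.34 MJ/kg DM of urinary + methane losses
  expect_equal(diet_me(16.05, 0.34e3 * dmi, 0, dmi), 15.71)
  expect_equal(diet_me(16.05, 0, 0, dmi), 16.05)
  expect_warning(diet_me(0.1, 1e3, 0, 1), "negative ME")

  expect_equal(retained_energy(2311, 1196), 1115)
  expect_equal(retained_energy(2228, 1213), 1015)
  expect_equal(retained_energy(1500, 1500), 0)

  expect_equal(retained_energy_protein(0), 0)
  expect_equal(retained_energy_protein(1), 149.125)
  expect_equal(retained_energy_protein(28.2), 4205.325)

  expect_equal(diet_ne(0, 0, 1.4), 0)
  # basal NE/ME ratio: (RE + FHP)/MEI = 1920/2311
  expect_equal(100 * diet_ne(1115, 805, 1) / diet_ne(2311, 0, 1),
               83.08, tolerance = 5e-3)
  expect_error(diet_ne(100, 100, 0), "positive")
})

test_that("THP covariance adjustment moves pigs along a common slope", {
  # collinear case: adjusted values all meet at the reference intake
  thp <- c(1100, 1200, 1300); mei <- c(2100, 2254, 2408)
  adj <- adjust_thp_for_mei(thp, mei, 2254)
  expect_equal(adj, rep(1200, 3))
  b <- sum((mei - mean(mei)) * (thp - mean(thp))) / sum((mei - mean(mei))^2)
  expect_equal(adj, thp + b * (2254 - mei))

  # THP = 0.5 MEI exactly -> adjusted = 0.5 MEI_ref everywhere
  mei2 <- c(2000, 2200, 2500, 2300)
  expect_equal(adjust_thp_for_mei(0.5 * mei2, mei2, 2254), rep(1127, 4))

  # all MEI at the reference -> adjusted equals raw
  expect_warning(out <- adjust_thp_for_mei(thp, rep(2254, 3), 2254),
                 "no variation")
  expect_equal(out, thp)

  # period mean unchanged when mean(MEI) equals the reference
  set.seed(11)
  mei3 <- 2254 + scale(rnorm(6), scale = FALSE)[, 1]
  thp3 <- 400 + 0.4 * mei3 + rnorm(6, 0, 30)
  expect_equal(mean(adjust_thp_for_mei(thp3, mei3, 2254)), mean(thp3))
})

test_that("per-pig pipeline recovers ground truth and conserves energy", {
  cfg <- simulation_config(seed = 101, noise_cv = 0)
  sim <- simulate_experiment(cfg, study$diets)
  eb <- energy_balance(sim$chamber_records, sim$balance_records)
  diet <- aggregate_by_diet(eb)
  m <- merge(diet, sim$truth$diet_energy, by = "diet_id",
             suffixes = c("", ".true"))
  for (v in c("DE", "ME", "NE"))
    expect_lt(max(abs(m[[v]] / m[[paste0(v, ".true")]] - 1)), 1e-3)
  p <- merge(eb, sim$truth$pig_energy, by = "pig_id",
             suffixes = c("", ".true"))
  expect_lt(max(abs(p$THP / p$THP.true - 1)), 1e-3)
  expect_lt(max(abs(p$FHP / p$FHP.true - 1)), 1e-3)

  # ordering NE <= ME <= DE <= GE and per-pig energy conservation
  ge <- study$diets$chemistry$GE[match(eb$diet_id, study$diets$chemistry$diet_id)]
  expect_true(all(eb$NE <= eb$ME & eb$ME <= eb$DE & eb$DE <= ge))
  bal <- sim$balance_records[match(eb$pig_id, sim$balance_records$pig_id), ]
  mbw <- eb$BW_kg^0.6
  ch4e <- eb$CH4E_over_DE / 100 * eb$DE * 1e3 * eb$DMI_kg_d
  lhs <- bal$GE_intake_kJ_d
  rhs <- bal$fecal_GE_kJ_d + bal$urine_E_kJ_d + ch4e +
    eb$THP * mbw + eb$RE * mbw
  expect_equal(lhs, rhs, tolerance = 1e-8)

  # recovered NE/DMI identity: NE x DMI = (RE + FHP) x BW^0.6
  expect_equal(eb$NE * 1e3 * eb$DMI_kg_d, (eb$RE + eb$FHP) * mbw,
               tolerance = 1e-8)
  expect_equal(eb$REL, eb$RE - eb$REP)
})

test_that("diet means with default noise stay near truth at n = 6", {
  cfg <- simulation_config(seed = 202)  # default 3% measurement noise
  sim <- simulate_experiment(cfg, study$diets)
  eb <- energy_balance(sim$chamber_records, sim$balance_records)
  diet <- aggregate_by_diet(eb)
  m <- merge(diet, sim$truth$diet_energy, by = "diet_id",
             suffixes = c("", ".true"))
  expect_lt(max(abs(m$NE / m$NE.true - 1)), 0.02)
  expect_lt(max(abs(m$DE / m$DE.true - 1)), 0.02)
})

test_that("diet aggregation is the arithmetic mean by diet", {
  df <- data.frame(diet_id = c("A", "A", "B"), DE = c(16.0, 16.1, 14.0),
                   NE = c(13, 13.4, 11))
  agg <- aggregate_by_diet(df)
  expect_equal(agg$DE[agg$diet_id == "A"], 16.05)
  expect_equal(agg$n_pigs, c(2, 1))
  one <- aggregate_by_diet(df[3, ])
  expect_equal(one$DE, 14.0)
})
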