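## Digestibility, nitrogen balance and the diet-level energy partition
## (DE -> ME -> NE) per pig and per diet, including the covariance
## adjustment of total heat production to a reference ME intake.

#' Apparent total tract digestibility
#'
#' ATTD (%) = 100 x (intake - fecal output) / intake, for energy (kJ) or a
#' nutrient (g) over a collection period.
#'
#' @param fi Total intake over the period (kJ or g); must be positive.
#' @param ff Total fecal output over the period, same units.
#' @return ATTD, %. Fecal output exceeding intake yields a negative value
#'   with a warning (flagged, not an error).
#' @examples
#' attd(41.2, 5.4)
#' @export
attd <- function(fi, ff) {
  stopifnot(is.numeric(fi), is.numeric(ff))
  if (any(fi <= 0)) stop("intake must be positive")
  if (any(ff < 0)) stop("fecal output must be nonnegative")
  if (any(ff > fi)) warning("fecal output exceeds intake: negative digestibility")
  100 * (fi - ff) / fi
}

#' Nitrogen retention
#'
#' Retention (g/d) = intake - fecal output - urinary output.
#'
#' @param intake,fecal,urinary Nitrogen flows, g/d, all nonnegative.
#' @return Nitrogen retained, g/d.
#' @examples
#' nitrogen_balance(41.2, 5.4, 7.7)
#' @export
nitrogen_balance <- function(intake, fecal, urinary) {
  if (any(c(intake, fecal, urinary) < 0)) stop("nitrogen flows must be nonnegative")
  intake - fecal - urinary
}

#' Digestible energy of a diet
#'
#' DE (MJ/kg DM) = (GE intake - fecal GE) / DM intake.
#'
#' @param ge_intake_kj GE intake, kJ/d.
#' @param fecal_ge_kj Fecal gross energy, kJ/d.
#' @param dmi DM intake, kg/d; must be positive.
#' @return DE, MJ/kg DM.
#' @export
diet_de <- function(ge_intake_kj, fecal_ge_kj, dmi) {
  if (any(dmi <= 0)) stop("DM intake must be positive")
  kj_to_mj((ge_intake_kj - fecal_ge_kj) / dmi)
}

#' Metabolizable energy of a diet
#'
#' ME is DE minus urinary energy and methane energy:
#' ME (MJ/kg DM) = DE - (urine energy + 39.5 x CH4) / DM intake.
#'
#' @param de DE, MJ/kg DM.
#' @param urine_energy_kj Urinary energy, kJ/d.
#' @param ch4_l Methane production, L/d.
#' @param dmi DM intake, kg/d.
#' @return ME, MJ/kg DM. A negative result is flagged with a warning.
#' @export
diet_me <- function(de, urine_energy_kj, ch4_l, dmi) {
  if (any(c(urine_energy_kj, ch4_l) < 0)) stop("losses must be nonnegative")
  if (any(dmi <= 0)) stop("DM intake must be positive")
  me <- de - kj_to_mj(urine_energy_kj + methane_energy(ch4_l)) / dmi
  if (any(me < 0)) warning("negative ME: losses exceed DE")
  me
}

#' Retained energy
#'
#' RE = ME intake - total heat production, on a common basis (typically
#' kJ/kg BW^0.60/d).
#'
#' @param mei ME intake.
#' @param thp Total heat production, same basis.
#' @return RE, same basis.
#' @examples
#' retained_energy(2311, 1196)
#' @export
retained_energy <- function(mei, thp) {
  if (any(mei < 0)) stop("ME intake must be nonnegative")
  mei - thp
}

#' Retained energy as protein
#'
#' REP (kJ/d) = N retention (g/d) x 6.25 x 23.86 kJ/g protein.
#'
#' @param n_retention Nitrogen retained, g/d.
#' @return REP, kJ/d.
#' @examples
#' retained_energy_protein(28.2)
#' @export
retained_energy_protein <- function(n_retention) {
  n_retention * N_TO_CP * PROTEIN_KJ_PER_G
}

#' Net energy of a diet
#'
#' NE (MJ/kg DM) = (RE + FHP) / DM intake, with RE and FHP in kJ/d.
#'
#' @param re_kj Retained energy, kJ/d.
#' @param fhp_kj Fasting heat production, kJ/d.
#' @param dmi DM intake, kg/d.
#' @return NE, MJ/kg DM.
#' @export
diet_ne <- function(re_kj, fhp_kj, dmi) {
  if (any(dmi <= 0)) stop("DM intake must be positive")
  kj_to_mj((re_kj + fhp_kj) / dmi)
}

#' Adjust heat production to a reference ME intake by covariance
#'
#' Heat production rises with ME intake, so diet comparisons adjust THP to a
#' common reference intake. Within one collection period a single straight
#' line THP = a + b MEI is fitted across pigs (pooled over diets) and each
#' pig's THP is moved along that slope:
#' adjusted THP_i = THP_i + b (MEI_ref - MEI_i).
#'
#' @param thp Total heat production per pig, kJ/kg BW^0.60/d.
#' @param mei ME intake per pig, same basis.
#' @param mei_ref Reference ME intake, default 2254 kJ/kg BW^0.60/d (the
#'   experiment-wide mean of the reference dataset).
#' @return Numeric vector of adjusted THP. If all MEI are identical the
#'   slope is undefined and the raw THP is returned with a warning.
#' @examples
#' adjust_thp_for_mei(c(1100, 1200, 1300), c(2100, 2254, 2408))
#' @export
adjust_thp_for_mei <- function(thp, mei, mei_ref = 2254) {
  stopifnot(length(thp) == length(mei))
  if (length(thp) < 2 || stats::var(mei) == 0) {
    warning("no variation in ME intake: returning unadjusted THP")
    return(thp)
  }
  b <- unname(stats::coef(stats::lm(thp ~ mei))[2])
  thp + b * (mei_ref - mei)
}

.daily_hp <- function(rows) {
  # daily heat production per chamber-day from cumulative daily gas volumes
  brouwer_hp(rows$O2_L, rows$CO2_L, rows$CH4_L, rows$urine_N_g) *
    24 / rows$duration_h
}

#' Per-pig energy balance from chamber and collection records
#'
#' The workhorse of the pipeline: combines respiration-chamber gas records
#' with total-collection balance records into one row per pig x period with
#' digestibilities, nitrogen balance, the energy partition (DE, ME, NE), heat
#' production (THP, covariance-adjusted THP, FHP), retained energy and its
#' protein/lipid split, respiratory quotients, and utilization ratios.
#'
#' `chamber_records` needs columns `pig_id, period, diet_id, BW_kg, day,
#' state` (`"fed"` or `"fasting"`), `O2_L, CO2_L, CH4_L, urine_N_g,
#' duration_h`; multi-day fed heat production is the mean of daily values.
#' `balance_records` needs `pig_id, period, diet_id, BW_kg, DMI_kg_d,
#' GE_intake_kJ_d, fecal_GE_kJ_d, N_intake_g_d, fecal_N_g_d, urine_N_g_d,
#' urine_E_kJ_d` and optionally paired `<X>_intake_g_d` / `fecal_<X>_g_d`
#' columns for DM, OM, NDF, ADF digestibilities.
#'
#' @param chamber_records Data.frame of gas-exchange records.
#' @param balance_records Data.frame of intake/output records.
#' @param mei_ref Reference ME intake for THP adjustment (kJ/kg BW^0.60/d).
#' @return A data.frame of class `energy_balance`, one row per pig x period:
#'   energy flows in kJ/kg BW^0.60/d, energy values in MJ/kg DM, ATTD and
#'   utilization ratios in %.
#' @seealso [aggregate_by_diet()] for diet means.
#' @export
energy_balance <- function(chamber_records, balance_records, mei_ref = 2254) {
  stopifnot(is.data.frame(chamber_records), is.data.frame(balance_records))
  bal <- balance_records
  if (any(bal$DMI_kg_d <= 0)) stop("DM intake must be positive")
  out <- lapply(seq_len(nrow(bal)), function(i) {
    b <- bal[i, ]
    ch <- chamber_records[chamber_records$pig_id == b$pig_id &
                            chamber_records$period == b$period, ]
    fed <- ch[ch$state == "fed", ]
    fast <- ch[ch$state == "fasting", ]
    if (nrow(fed) == 0) stop("no fed-state chamber record for pig ", b$pig_id)
    if (nrow(fast) == 0) stop("no fasting chamber record for pig ", b$pig_id)
    mbw <- metabolic_bw(b$BW_kg)

    de <- diet_de(b$GE_intake_kJ_d, b$fecal_GE_kJ_d, b$DMI_kg_d)
    ch4_daily <- mean(fed$CH4_L * 24 / fed$duration_h)
    me <- diet_me(de, b$urine_E_kJ_d, ch4_daily, b$DMI_kg_d)
    mei <- mj_to_kj(me) * b$DMI_kg_d / mbw

    thp <- mean(.daily_hp(fed)) / mbw
    fhp <- extrapolate_fhp(gas_window(fast$O2_L[1], fast$CO2_L[1],
                                      fast$CH4_L[1], fast$urine_N_g[1],
                                      fast$duration_h[1], b$BW_kg))$HP_daily / mbw
    re <- retained_energy(mei, thp)
    n_ret <- nitrogen_balance(b$N_intake_g_d, b$fecal_N_g_d, b$urine_N_g_d)
    rep_ <- retained_energy_protein(n_ret) / mbw
    rel <- re - rep_
    ne <- diet_ne(re * mbw, fhp * mbw, b$DMI_kg_d)

    de_intake_kj <- mj_to_kj(de) * b$DMI_kg_d
    res <- data.frame(
      pig_id = b$pig_id, period = b$period, diet_id = b$diet_id,
      BW_kg = b$BW_kg, DMI_kg_d = b$DMI_kg_d,
      ATTD_GE = attd(b$GE_intake_kJ_d, b$fecal_GE_kJ_d),
      ATTD_CP = attd(b$N_intake_g_d, b$fecal_N_g_d),
      N_retention_g_d = n_ret,
      DE = de, ME = me, NE = ne,
      UE_over_DE = 100 * b$urine_E_kJ_d / de_intake_kj,
      CH4E_over_DE = 100 * methane_energy(ch4_daily) / de_intake_kj,
      ME_over_DE = 100 * me / de, NE_over_ME = 100 * ne / me,
      MEI = mei, THP = thp, FHP = fhp,
      RE = re, REP = rep_, REL = rel,
      RQ_fed = mean(respiratory_quotient(fed$O2_L, fed$CO2_L)),
      RQ_fasted = respiratory_quotient(fast$O2_L[1], fast$CO2_L[1]))
    for (an in c("DM", "OM", "NDF", "ADF")) {
      ic <- paste0(an, "_intake_g_d"); fc <- paste0("fecal_", an, "_g_d")
      res[[paste0("ATTD_", an)]] <- if (all(c(ic, fc) %in% names(b)))
        attd(b[[ic]], b[[fc]]) else NA_real_
    }
    res
  })
  res <- do.call(rbind, out)
  res$adjTHP <- NA_real_
  for (p in unique(res$period)) {
    sel <- res$period == p
    res$adjTHP[sel] <- if (sum(sel) >= 3)
      adjust_thp_for_mei(res$THP[sel], res$MEI[sel], mei_ref) else res$THP[sel]
  }
  if (any(res$REL < 0))
    warning("negative retained energy as lipid (lipid mobilization) for ",
            sum(res$REL < 0), " pig(s)")
  class(res) <- c("energy_balance", "data.frame")
  res
}

#' Diet-level means of per-pig energy balance results
#'
#' Arithmetic means of every numeric column by diet (per-pig-first
#' aggregation: values are computed per pig, then averaged).
#'
#' @param results An `energy_balance` data.frame (or any data.frame with a
#'   `diet_id` column).
#' @return A data.frame with one row per diet plus `n_pigs`.
#' @export
aggregate_by_diet <- function(results) {
  stopifnot(is.data.frame(results), "diet_id" %in% names(results))
  num <- names(results)[vapply(results, is.numeric, logical(1))]
  agg <- stats::aggregate(results[num], by = list(diet_id = results$diet_id),
                          FUN = mean)
  n <- as.data.frame(table(diet_id = results$diet_id), stringsAsFactors = FALSE)
  names(n)[2] <- "n_pigs"
  merge(agg, n, by = "diet_id")
}
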