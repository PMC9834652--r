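## Respiration-chamber experiment simulator with known ground truth, plus
## the packaged reference dataset (a published wheat bran / wheat shorts
## evaluation in growing pigs).

#' Simulation configuration
#'
#' Study conditions for [simulate_experiment()]. Defaults are anchored to a
#' typical growing-pig chamber experiment with 30% wheat bran diets: 6 pigs
#' per diet of about 41 kg, dry-matter intake 0.156 kg/d per kg BW^0.60
#' (ME intake near 2,250 kJ/kg BW^0.60/d), GE digestibility 0.80, urinary
#' and methane losses 3.1% and 0.4% of DE, fed/fasted respiratory quotients
#' 1.08/0.82, fasting heat production 800 kJ/kg BW^0.60/d, NE/ME 0.80, and
#' protein accounting for 42% of retained energy.
#'
#' @param seed RNG seed (integer).
#' @param n_pigs_per_diet Pigs per dietary treatment.
#' @param bw_mean,bw_sd Body-weight distribution, kg.
#' @param dmi_per_mbw DM intake rule, kg/d per kg BW^0.60.
#' @param dmi_fixed Optional fixed DM intake, kg/d (overrides the rule).
#' @param attd_ge,attd_cp,attd_dm,attd_om,attd_ndf,attd_adf True
#'   digestibilities (0-1).
#' @param ue_over_de,ch4e_over_de Urinary and methane energy as fractions of
#'   DE (0-1).
#' @param rq_fed,rq_fasted Respiratory quotients, in \[0.7, 1.2\].
#' @param fhp True fasting heat production, kJ/kg BW^0.60/d.
#' @param ne_over_me Target NE as a fraction of ME (used when a diet has no
#'   explicit NE target).
#' @param rep_fraction Protein share of retained energy (0-1).
#' @param fasting_n_fraction Fasting urinary N as a fraction of the fed-state
#'   daily excretion, before prorating to the fasting window.
#' @param n_fed_days Fed chamber days per pig.
#' @param fasting_duration Fasting window length, h.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise on outputs and gas volumes (0 = exact).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_pigs_per_diet = 6,
                              bw_mean = 41, bw_sd = 2,
                              dmi_per_mbw = 0.156, dmi_fixed = NULL,
                              attd_ge = 0.80, attd_cp = 0.76, attd_dm = 0.81,
                              attd_om = 0.83, attd_ndf = 0.57, attd_adf = 0.43,
                              ue_over_de = 0.031, ch4e_over_de = 0.004,
                              rq_fed = 1.08, rq_fasted = 0.82,
                              fhp = 800, ne_over_me = 0.80,
                              rep_fraction = 0.42, fasting_n_fraction = 0.5,
                              n_fed_days = 5, fasting_duration = 8,
                              noise_cv = 0.03) {
  cfg <- as.list(environment())
  digs <- unlist(cfg[c("attd_ge", "attd_cp", "attd_dm", "attd_om",
                       "attd_ndf", "attd_adf")])
  if (any(digs < 0 | digs > 1)) stop("digestibilities must be in [0, 1]")
  fracs <- unlist(cfg[c("ue_over_de", "ch4e_over_de", "ne_over_me",
                        "rep_fraction", "fasting_n_fraction")])
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  rqs <- c(cfg$rq_fed, cfg$rq_fasted)
  if (any(rqs < 0.7 | rqs > 1.2)) stop("RQ must be in [0.7, 1.2]")
  if (cfg$fhp < 0 || cfg$noise_cv < 0 || cfg$bw_mean <= 0 || cfg$bw_sd < 0)
    stop("invalid configuration value")
  structure(cfg, class = "simulation_config")
}

.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a complete chamber experiment
#'
#' Generates per-pig chamber and balance records consistent with a known
#' ground truth. For each pig: body weight and DM intake are drawn; true
#' intakes follow the diet chemistry; fecal outputs are intake x (1 -
#' digestibility); urinary and methane energy are fixed fractions of DE;
#' retained energy is set from the diet's target NE via
#' RE = NE x DMI - FHP x BW^0.60, so THP = MEI - RE; daily gas volumes are
#' obtained by Brouwer inversion at the configured respiratory quotient
#' ([invert_brouwer()]); the fasting window is scaled to its duration at the
#' fasted RQ. Multiplicative measurement noise is applied last, to outputs
#' and gas volumes only, so energy is conserved in truth but not in the
#' measurements.
#'
#' @param config A [simulation_config()].
#' @param diets A `diet_table` ([read_diet_tables()]) supplying per-diet GE,
#'   CP, NDF, ADF, ash and DM.
#' @param diet_targets Optional data.frame of per-diet overrides: `diet_id`
#'   plus any of `NE` (MJ/kg DM), `attd_ge`, `attd_cp`, `ue_over_de`,
#'   `ch4e_over_de`.
#' @return A list of class `simulated_experiment`: `chamber_records`,
#'   `balance_records` (the CSV schemas consumed by [energy_balance()]) and
#'   `truth` (list with per-diet `diet_energy` and per-pig `pig_energy`).
#' @examples
#' d <- read_diet_tables(
#'   system.file("extdata", "wheat_diets.csv", package = "swineNE"),
#'   system.file("extdata", "wheat_diet_chemistry.csv", package = "swineNE"))
#' sim <- simulate_experiment(simulation_config(seed = 7, noise_cv = 0), d)
#' head(sim$truth$diet_energy)
#' @export
simulate_experiment <- function(config, diets, diet_targets = NULL) {
  stopifnot(inherits(config, "simulation_config"), inherits(diets, "diet_table"))
  set.seed(config$seed)
  chem <- diets$chemistry
  ids <- chem$diet_id
  per_diet <- function(d, field, default) {
    if (!is.null(diet_targets) && field %in% names(diet_targets)) {
      v <- diet_targets[[field]][diet_targets$diet_id == d]
      if (length(v) == 1 && !is.na(v)) return(v)
    }
    default
  }
  chamber <- balance <- truth_pig <- list()
  truth_diet <- list()
  pig_no <- 0
  for (d in ids) {
    ge <- chem$GE[chem$diet_id == d]       # MJ/kg DM
    cp <- chem$CP[chem$diet_id == d]       # % DM
    attd_ge <- per_diet(d, "attd_ge", config$attd_ge)
    attd_cp <- per_diet(d, "attd_cp", config$attd_cp)
    ue <- per_diet(d, "ue_over_de", config$ue_over_de)
    ch4e <- per_diet(d, "ch4e_over_de", config$ch4e_over_de)
    de_kj <- attd_ge * mj_to_kj(ge)                 # kJ/kg DM
    me_kj <- de_kj * (1 - ue - ch4e)
    ne_mj <- per_diet(d, "NE", config$ne_over_me * kj_to_mj(me_kj))
    ne_kj <- mj_to_kj(ne_mj)
    if (ne_kj > me_kj)
      stop(sprintf("infeasible config: diet '%s' NE target (%.2f) exceeds ME (%.2f MJ/kg DM)",
                   d, ne_mj, kj_to_mj(me_kj)))
    truth_diet[[d]] <- data.frame(diet_id = d, GE = ge,
                                  DE = kj_to_mj(de_kj), ME = kj_to_mj(me_kj),
                                  NE = ne_mj)
    for (j in seq_len(config$n_pigs_per_diet)) {
      pig_no <- pig_no + 1
      pig <- sprintf("pig%02d", pig_no)
      bw <- stats::rnorm(1, config$bw_mean, config$bw_sd)
      mbw <- metabolic_bw(bw)
      dmi <- config$dmi_fixed %||% (config$dmi_per_mbw * mbw)
      ge_in <- mj_to_kj(ge) * dmi                   # kJ/d
      fecal_ge <- (1 - attd_ge) * ge_in
      de_in <- attd_ge * ge_in
      urine_e <- ue * de_in
      ch4_l <- ch4e * de_in / CH4_KJ_PER_L          # L/d
      mei <- de_in - urine_e - ch4e * de_in         # kJ/d
      re <- ne_kj * dmi - config$fhp * mbw          # kJ/d
      thp <- mei - re
      if (thp <= 0)
        stop("infeasible config: nonpositive heat production for diet ", d)
      n_in <- cp / 100 * dmi * 1000 / N_TO_CP       # g/d
      fecal_n <- (1 - attd_cp) * n_in
      n_ret <- config$rep_fraction * re / (N_TO_CP * PROTEIN_KJ_PER_G)
      urine_n <- n_in - fecal_n - n_ret
      if (urine_n < 0)
        stop("infeasible config: negative urinary N for diet ", d)
      fed_gas <- invert_brouwer(thp, config$rq_fed, ch4_l, urine_n)
      fhp_d <- config$fhp * mbw
      fast_n <- config$fasting_n_fraction * urine_n *
        config$fasting_duration / 24
      fast_gas <- invert_brouwer(fhp_d * config$fasting_duration / 24,
                                 config$rq_fasted, 0, fast_n)
      nd <- config$n_fed_days
      cv <- config$noise_cv
      chamber[[pig]] <- data.frame(
        pig_id = pig, period = j, diet_id = d, BW_kg = bw,
        day = c(seq_len(nd), nd + 1),
        state = c(rep("fed", nd), "fasting"),
        O2_L = c(fed_gas$o2 * .lognoise(nd, cv), fast_gas$o2 * .lognoise(1, cv)),
        CO2_L = c(fed_gas$co2 * .lognoise(nd, cv), fast_gas$co2 * .lognoise(1, cv)),
        CH4_L = c(ch4_l * .lognoise(nd, cv), 0),
        urine_N_g = c(urine_n * .lognoise(nd, cv), fast_n * .lognoise(1, cv)),
        duration_h = c(rep(24, nd), config$fasting_duration))
      ndf <- chem$NDF[chem$diet_id == d]
      adf <- chem$ADF[chem$diet_id == d]
      ash <- chem$ash[chem$diet_id == d]
      balance[[pig]] <- data.frame(
        pig_id = pig, period = j, diet_id = d, BW_kg = bw, DMI_kg_d = dmi,
        GE_intake_kJ_d = ge_in,
        fecal_GE_kJ_d = fecal_ge * .lognoise(1, cv),
        N_intake_g_d = n_in,
        fecal_N_g_d = fecal_n * .lognoise(1, cv),
        urine_N_g_d = urine_n * .lognoise(1, cv),
        urine_E_kJ_d = urine_e * .lognoise(1, cv),
        DM_intake_g_d = dmi * 1000,
        fecal_DM_g_d = (1 - config$attd_dm) * dmi * 1000 * .lognoise(1, cv),
        OM_intake_g_d = (100 - ash) / 100 * dmi * 1000,
        fecal_OM_g_d = (1 - config$attd_om) * (100 - ash) / 100 * dmi * 1000 *
          .lognoise(1, cv),
        NDF_intake_g_d = ndf / 100 * dmi * 1000,
        fecal_NDF_g_d = (1 - config$attd_ndf) * ndf / 100 * dmi * 1000 *
          .lognoise(1, cv),
        ADF_intake_g_d = adf / 100 * dmi * 1000,
        fecal_ADF_g_d = (1 - config$attd_adf) * adf / 100 * dmi * 1000 *
          .lognoise(1, cv))
      truth_pig[[pig]] <- data.frame(
        pig_id = pig, diet_id = d, BW_kg = bw,
        THP = thp / mbw, FHP = config$fhp, RE = re / mbw)
    }
  }
  structure(list(
    chamber_records = do.call(rbind, unname(chamber)),
    balance_records = do.call(rbind, unname(balance)),
    truth = list(diet_energy = do.call(rbind, unname(truth_diet)),
                 pig_energy = do.call(rbind, unname(truth_pig)))),
    class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("Simulated chamber experiment:",
      nrow(x$truth$pig_energy), "pigs,",
      nrow(x$truth$diet_energy), "diets\n")
  invisible(x)
}

#' Packaged reference dataset: wheat bran and wheat shorts in growing pigs
#'
#' The published evaluation this package ships as its worked example: six
#' wheat bran samples and one wheat shorts fed at 30% inclusion in
#' corn-soybean-meal diets to growing barrows, with ingredient chemistry,
#' diet formulations and analyzed chemistry, diet-level energy balance means
#' (n = 6 pigs), and ingredient-level energy values with Noblet-equation
#' validation.
#'
#' @return A list with `ingredients` (validated `ingredient_table`),
#'   `diets` (`diet_table`), `diet_energy` (per-diet means: energy flows in
#'   kJ/kg BW^0.60/d, DE/ME/NE in MJ/kg DM, ratios in %), and
#'   `ingredient_energy` (per-ingredient ATTD, utilization ratios, DE/ME/NE,
#'   predicted NE and relative error).
#' @examples
#' study <- wheat_bran_study()
#' study$ingredient_energy[, c("ingredient_id", "NE")]
#' @export
wheat_bran_study <- function() {
  path <- function(f) system.file("extdata", f, package = "swineNE",
                                  mustWork = TRUE)
  list(
    ingredients = read_ingredient_table(path("wheat_ingredients.csv")),
    diets = read_diet_tables(path("wheat_diets.csv"),
                             path("wheat_diet_chemistry.csv")),
    diet_energy = utils::read.csv(path("wheat_diet_energy.csv"),
                                  stringsAsFactors = FALSE),
    ingredient_energy = utils::read.csv(path("wheat_ingredient_energy.csv"),
                                        stringsAsFactors = FALSE))
}
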