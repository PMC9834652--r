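## Ingredient-level energy values by the difference method: subtract the
## basal-mixture contribution from each test diet, scale by the test
## inclusion, then correct the whole chain by the ratio of the ingredient's
## measured GE to its calculated-by-difference GE.

#' Energy of the basal reference mixture
#'
#' The GE/DE/ME/NE of the corn-soybean-meal-amino-acid mixture is obtained
#' by dividing the basal diet's value by the mixture's share of that diet
#' (the mineral/vitamin remainder is treated as energy-free).
#'
#' @param basal_energy Basal-diet energy value(s), MJ/kg DM.
#' @param mixture_fraction Proportion of the basal diet that is mixture,
#'   default 0.97.
#' @return Mixture energy, MJ/kg DM.
#' @examples
#' basal_mixture_energy(16.05, 0.97)
#' @export
basal_mixture_energy <- function(basal_energy, mixture_fraction = 0.97) {
  if (any(mixture_fraction <= 0) || any(mixture_fraction > 1))
    stop("mixture fraction must be in (0, 1]")
  basal_energy / mixture_fraction
}

#' Test-ingredient energy by the difference method
#'
#' E_ingredient = (E_test_diet - f_mix x E_mixture) / f_test, where f_mix and
#' f_test are the proportions of the test diet that are basal mixture and
#' test ingredient. The mixture's energy is assumed identical across diets.
#'
#' @param test_diet_energy Test-diet energy, MJ/kg DM.
#' @param mixture_energy Basal-mixture energy, MJ/kg DM.
#' @param f_mix Proportion of the test diet that is mixture (0-1).
#' @param f_test Proportion that is test ingredient (0-1); must be positive.
#' @param tol Slack on f_mix + f_test <= 1 + tol for mineral carriers.
#' @return Ingredient energy, MJ/kg DM. Negative results are flagged with a
#'   warning and returned.
#' @examples
#' energy_by_difference(14.27, 16.55, f_mix = 0.6735, f_test = 0.30)
#' @export
energy_by_difference <- function(test_diet_energy, mixture_energy,
                                 f_mix, f_test, tol = 1e-6) {
  if (any(f_test <= 0)) stop("test-ingredient fraction must be positive")
  if (any(f_mix < 0)) stop("mixture fraction must be nonnegative")
  if (any(f_mix + f_test > 1 + tol))
    stop("mixture and test fractions exceed the whole diet")
  e <- (test_diet_energy - f_mix * mixture_energy) / f_test
  if (any(e < 0)) warning("negative ingredient energy by difference")
  e
}

#' Final ingredient energy values via the measured-GE ratio chain
#'
#' The difference method yields calculated values GEc, DEc, MEc, NEc that
#' inherit sampling error from both diets. The final values are anchored to
#' the ingredient's bomb-calorimetry GE (GEm) through the ratio chain
#' DE = GEm x DEc/GEc, ME = DE x MEc/DEc, NE = ME x NEc/MEc, which collapses
#' to NE = GEm x NEc/GEc.
#'
#' @param gec,dec,mec,nec Calculated-by-difference GE, DE, ME, NE, MJ/kg DM;
#'   GEc, DEc and MEc must be positive.
#' @param gem Measured ingredient GE, MJ/kg DM.
#' @return A one-row data.frame with `GEc, DEc, MEc, NEc, GEm`, the finals
#'   `DE, ME, NE` and the ratios `DE_over_GE, ME_over_DE, NE_over_ME` (%).
#' @examples
#' finalize_with_ge_ratio(gec = 18.59, dec = 10.42, mec = 9.62, nec = 6.47,
#'                        gem = 18.72)
#' @export
finalize_with_ge_ratio <- function(gec, dec, mec, nec, gem) {
  if (any(c(gec, dec, mec) <= 0))
    stop("calculated GE, DE and ME must be positive")
  de <- gem * dec / gec
  me <- de * mec / dec
  ne <- me * nec / mec
  data.frame(GEc = gec, DEc = dec, MEc = mec, NEc = nec, GEm = gem,
             DE = de, ME = me, NE = ne,
             DE_over_GE = 100 * de / gem, ME_over_DE = 100 * me / de,
             NE_over_ME = 100 * ne / me)
}

# Mixture/test fractions of one test diet on the requested basis.
# DM basis: the test share is inclusion x ingredient DM over total diet DM;
# the non-test portion's DM content is inferred from the analyzed diet DM
# (corn/soybean-meal DM is not observed separately).
.diet_fractions <- function(diets, diet_id, ingredients,
                            basis = c("DM", "as-fed")) {
  basis <- match.arg(basis)
  fr <- diet_mixture_fraction(diets, diet_id)
  if (basis == "as-fed" || is.na(fr$test_id)) return(fr)
  chem <- diets$chemistry
  dm_diet <- chem$DM[chem$diet_id == diet_id]
  dm_test <- ingredients$DM[ingredients$ingredient_id == fr$test_id]
  if (length(dm_test) == 0)
    stop("test ingredient '", fr$test_id, "' not in ingredient table")
  test_dm_share <- fr$f_test * dm_test / dm_diet
  dm_nontest <- (dm_diet - fr$f_test * dm_test) / (1 - fr$f_test)
  fr$f_test <- test_dm_share
  fr$f_mix <- fr$f_mix * dm_nontest / dm_diet
  fr
}

#' Ingredient energy values from diet energy values
#'
#' Applies the difference method to every test diet: derives the basal
#' mixture's GE/DE/ME/NE from the basal diet, subtracts its contribution
#' from each test diet, scales by the test-ingredient inclusion, and anchors
#' the result to the ingredient's measured GE
#' ([finalize_with_ge_ratio()]).
#'
#' @param diet_energy Data.frame with columns `diet_id, GE, DE, ME, NE`
#'   (MJ/kg DM); diet GE is the analyzed diet chemistry value.
#' @param diets A `diet_table` ([read_diet_tables()]).
#' @param ingredients An `ingredient_table` with measured GE and DM of the
#'   test ingredients.
#' @param mixture_fraction Mixture share of the basal diet, default 0.97.
#' @param basis `"DM"` (default) converts as-fed inclusions to dry-matter
#'   fractions; `"as-fed"` uses the formulation fractions directly.
#' @return A data.frame of class `ingredient_energy`, one row per test
#'   ingredient, with the difference-method intermediates, finals and ratios
#'   of [finalize_with_ge_ratio()].
#' @export
ingredient_energy <- function(diet_energy, diets, ingredients,
                              mixture_fraction = 0.97,
                              basis = c("DM", "as-fed")) {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(diet_energy),
            all(c("diet_id", "GE", "DE", "ME", "NE") %in% names(diet_energy)))
  info <- lapply(diet_energy$diet_id, function(d)
    .diet_fractions(diets, d, ingredients, basis))
  is_basal <- vapply(info, function(f) is.na(f$test_id), logical(1))
  if (sum(is_basal) != 1)
    stop("need exactly one basal diet (no test ingredient); found ",
         sum(is_basal))
  basal <- diet_energy[is_basal, ]
  mix <- lapply(basal[c("GE", "DE", "ME", "NE")],
                basal_mixture_energy, mixture_fraction = mixture_fraction)
  rows <- lapply(which(!is_basal), function(i) {
    fr <- info[[i]]
    calc <- lapply(c(GE = "GE", DE = "DE", ME = "ME", NE = "NE"), function(e)
      energy_by_difference(diet_energy[[e]][i], mix[[e]], fr$f_mix, fr$f_test))
    gem <- ingredients$GE[ingredients$ingredient_id == fr$test_id]
    out <- finalize_with_ge_ratio(calc$GE, calc$DE, calc$ME, calc$NE, gem)
    cbind(ingredient_id = fr$test_id, diet_id = diet_energy$diet_id[i], out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("ingredient_energy", "data.frame")
  res
}
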