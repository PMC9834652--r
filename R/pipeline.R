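## Orchestration: one call from raw records to diet balance, ingredient
## energy values and NE prediction statistics; plus recomputation of every
## derivable cell of the packaged reference dataset.

#' Run the full energy-evaluation analysis
#'
#' Executes the whole pipeline in the order the data are produced: per-pig
#' energy balance from chamber and collection records, diet-level means,
#' ingredient energy values by the difference method, Noblet-prediction
#' validation, and (given at least three test ingredients) the Pearson
#' correlation screen and NE prediction equations.
#'
#' @param ingredients An `ingredient_table` ([read_ingredient_table()]).
#' @param diets A `diet_table` ([read_diet_tables()]).
#' @param chamber_records,balance_records Records as consumed by
#'   [energy_balance()].
#' @param mei_ref Reference ME intake for THP adjustment, kJ/kg BW^0.60/d.
#' @param mixture_fraction Mixture share of the basal diet.
#' @param basis Inclusion-fraction basis for the difference method.
#' @param regression_ingredients Ingredients used for correlations and
#'   prediction equations; default all test ingredients. Supply e.g. only
#'   the wheat bran samples to exclude an ingredient of a different class.
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV together with a `manifest.csv` of file names and MD5
#'   content hashes.
#' @return A list of class `ne_analysis`: `pig_balance`, `diet_balance`,
#'   `diet_energy`, `ingredient_energy`, `noblet`, and when estimable
#'   `correlations` (a `correlation_matrix`) and `equations` (list of
#'   `ne_regression`).
#' @export
run_energy_analysis <- function(ingredients, diets, chamber_records,
                                balance_records, mei_ref = 2254,
                                mixture_fraction = 0.97,
                                basis = c("DM", "as-fed"),
                                regression_ingredients = NULL,
                                out_dir = NULL) {
  basis <- match.arg(basis)
  pig_balance <- energy_balance(chamber_records, balance_records, mei_ref)
  diet_balance <- aggregate_by_diet(pig_balance)
  chem <- diets$chemistry
  diet_energy <- merge(chem[c("diet_id", "GE")],
                       diet_balance[c("diet_id", "DE", "ME", "NE")],
                       by = "diet_id")
  ing_energy <- ingredient_energy(diet_energy, diets, ingredients,
                                  mixture_fraction, basis)
  noblet <- noblet_validation(ing_energy, ingredients)
  res <- list(pig_balance = pig_balance, diet_balance = diet_balance,
              diet_energy = diet_energy, ingredient_energy = ing_energy,
              noblet = noblet)
  reg_ids <- regression_ingredients %||% ing_energy$ingredient_id
  reg <- merge(ingredients[ingredients$ingredient_id %in% reg_ids, ],
               ing_energy[c("ingredient_id", "DE", "ME", "NE", "NE_over_ME")],
               by = "ingredient_id")
  if (nrow(reg) >= 3) {
    chem_vars <- c("CP", "EE", "starch", "NDF", "ADF", "IDF", "SDF", "TDF", "ash")
    res$correlations <- pearson_matrix(reg, c("GE", chem_vars, "DE", "ME",
                                              "NE", "NE_over_ME"))
    res$equations <- ne_equation_families(reg)
  }
  if (!is.null(out_dir)) .write_bundle(res, out_dir)
  class(res) <- c("ne_analysis", "list")
  res
}

# The three candidate families for NE prediction equations: proximate
# chemistry with and without GE, and the energy-only pair {GE, ME}; simple
# single-predictor fits are reported alongside the stepwise selections.
ne_equation_families <- function(reg, entry_alpha = 0.15, stay_alpha = 0.15) {
  chem <- intersect(c("CP", "EE", "starch", "NDF", "ADF", "ash"), names(reg))
  out <- list()
  add <- function(models) for (m in models)
    out[[paste(sort(m$predictors), collapse = "+")]] <<- m
  add(stepwise_select(reg, "NE", c("GE", chem), entry_alpha, stay_alpha))
  add(stepwise_select(reg, "NE", chem, entry_alpha, stay_alpha))
  add(stepwise_select(reg, "NE", c("GE", "ME"), entry_alpha, stay_alpha))
  for (v in c("CP", "NDF", "ADF", "ME"))
    out[[v]] <- out[[v]] %||% ols_fit(reg, "NE", v)
  ord <- order(-vapply(out, `[[`, numeric(1), "r.squared"),
               vapply(out, `[[`, numeric(1), "rmse"))
  unname(out[ord])
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(pig_balance = "pig_balance.csv", diet_balance = "diet_balance.csv",
             ingredient_energy = "ingredient_energy.csv",
             noblet = "noblet_validation.csv")
  written <- character(0)
  for (nm in names(files)) {
    p <- file.path(out_dir, files[[nm]])
    utils::write.csv(res[[nm]], p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(res$correlations)) {
    p <- file.path(out_dir, "correlations.csv")
    utils::write.csv(as.data.frame(res$correlations$r), p)
    written <- c(written, p)
  }
  if (!is.null(res$equations)) {
    eq <- do.call(rbind, lapply(res$equations, function(m) data.frame(
      equation = paste0(m$response, " = ",
                        paste(sprintf("%.2f", m$coefficients[1]),
                              paste(sprintf("%+.2f x %s", m$coefficients[-1],
                                            m$predictors), collapse = " "))),
      r.squared = m$r.squared, rmse = m$rmse, aic = m$aic, bic = m$bic,
      p.value = m$p.value)))
    p <- file.path(out_dir, "equations.csv")
    utils::write.csv(eq, p, row.names = FALSE)
    written <- c(written, p)
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(written)
}

#' @export
print.ne_analysis <- function(x, ...) {
  cat("Energy evaluation:", nrow(x$pig_balance), "pig-periods,",
      nrow(x$diet_balance), "diets,",
      nrow(x$ingredient_energy), "test ingredients\n")
  invisible(x)
}

#' Recompute every derivable cell of the packaged reference dataset
#'
#' From the packaged printed tables ([wheat_bran_study()]) recomputes every
#' quantity that follows from printed inputs — Noblet predicted NE and
#' relative errors, ME/DE and NE/ME ratios, correlations between wheat bran
#' chemistry and energy values, and the NE prediction equations — and
#' compares computed with printed at tolerances reflecting the tables'
#' printed precision (0.01 for correlations, coefficients and R2; 0.01 MJ
#' for energies; 0.055 for one-decimal percentages).
#'
#' Known, documented discrepancies are excluded and listed in the
#' `exceptions` attribute: the printed wheat-shorts predicted NE does not
#' follow from the stated equations (its relative error does, from the
#' printed predictions); the NE/ME and IDF correlation rows are inconsistent
#' with the other printed tables; the composition CVs follow no single sd convention
#' for every analyte; and the RMSE printed for the two chemistry-based
#' multi/single-predictor equations appear interchanged.
#'
#' @return A data.frame with columns `table, item, computed, printed,
#'   tolerance, pass`, with attribute `exceptions` (character vector).
#' @examples
#' chk <- validate_reference_tables()
#' all(chk$pass)
#' @export
validate_reference_tables <- function() {
  study <- wheat_bran_study()
  ing <- study$ingredients
  ie <- study$ingredient_energy
  brans <- merge(ing, ie, by = "ingredient_id",
                 suffixes = c("", ".printed"))
  brans <- brans[grepl("bran", brans$ingredient_id), ]
  rows <- list()
  note <- function(table, item, computed, printed, tolerance) {
    rows[[length(rows) + 1]] <<- data.frame(
      table = table, item = item, computed = computed, printed = printed,
      tolerance = tolerance, pass = abs(computed - printed) <= tolerance)
  }
  # Noblet predictions and relative errors (wheat bran only)
  ne1 <- noblet_ne1(brans$DE, brans$EE, brans$starch, brans$CP, brans$ADF)
  ne2 <- noblet_ne2(brans$ME, brans$EE, brans$starch, brans$CP, brans$ADF)
  re <- relative_error(brans$NE, ne1, ne2)
  for (i in seq_len(nrow(brans))) {
    id <- brans$ingredient_id[i]
    note("noblet", paste0(id, ":NE1"), ne1[i], brans$predicted_NE1[i], 0.01)
    note("noblet", paste0(id, ":NE2"), ne2[i], brans$predicted_NE2[i], 0.01)
    note("noblet", paste0(id, ":rel_err"), re[i], brans$relative_error[i], 0.055)
  }
  shorts <- ie[ie$ingredient_id == "wheat_shorts", ]
  note("noblet", "wheat_shorts:rel_err",
       relative_error(shorts$NE, shorts$predicted_NE1, shorts$predicted_NE2),
       shorts$relative_error, 0.055)
  # utilization ratios from printed finals
  for (i in seq_len(nrow(ie))) {
    id <- ie$ingredient_id[i]
    note("ratios", paste0(id, ":ME/DE"), 100 * ie$ME[i] / ie$DE[i],
         ie$ME_over_DE[i], 0.055)
    note("ratios", paste0(id, ":NE/ME"), 100 * ie$NE[i] / ie$ME[i],
         ie$NE_over_ME[i], 0.055)
  }
  # correlations between chemistry and energy values (bran samples)
  printed_r <- list(
    c("CP", "DE", 0.92), c("CP", "ME", 0.93), c("CP", "NE", 0.92),
    c("NDF", "DE", -0.88), c("NDF", "ME", -0.88), c("NDF", "NE", -0.84),
    c("ADF", "DE", -0.84), c("ADF", "ME", -0.85), c("ADF", "NE", -0.83),
    c("TDF", "DE", -0.82), c("TDF", "ME", -0.84), c("TDF", "NE", -0.72),
    c("ash", "DE", -0.84), c("ash", "ME", -0.83), c("ash", "NE", -0.76),
    c("GE", "NE", 0.79), c("starch", "NDF", -0.94), c("CP", "NDF", -0.83),
    c("DE", "ME", 0.99), c("DE", "NE", 0.93), c("ME", "NE", 0.92))
  cm <- pearson_matrix(brans, c("GE", "CP", "EE", "starch", "NDF", "ADF",
                                "IDF", "SDF", "TDF", "ash", "DE", "ME", "NE"))
  for (pr in printed_r)
    note("correlations", paste0("r(", pr[1], ",", pr[2], ")"),
         cm$r[pr[1], pr[2]], as.numeric(pr[3]), 0.01)
  # prediction equations: coefficients and R2
  printed_eq <- list(
    list(pred = c("GE", "CP"), coef = c(-21.65, 1.20, 0.35), r2 = 0.94),
    list(pred = "CP", coef = c(-0.80, 0.46), r2 = 0.85),
    list(pred = "NDF", coef = c(11.16, -0.09), r2 = 0.71),
    list(pred = "ADF", coef = c(10.51, -0.27), r2 = 0.68),
    list(pred = c("GE", "ME"), coef = c(-20.55, 1.20, 0.47), r2 = 0.94),
    list(pred = "ME", coef = c(0.77, 0.62), r2 = 0.85))
  for (eq in printed_eq) {
    m <- ols_fit(brans, "NE", eq$pred)
    lbl <- paste(eq$pred, collapse = "+")
    for (j in seq_along(m$coefficients))
      note("equations", paste0(lbl, ":b", j - 1),
           unname(m$coefficients[j]), eq$coef[j], 0.01)
    note("equations", paste0(lbl, ":R2"), m$r.squared, eq$r2, 0.01)
  }
  out <- do.call(rbind, rows)
  attr(out, "exceptions") <- c(
    "wheat shorts predicted NE1/NE2 do not follow from the stated equations",
    "NE/ME correlation row inconsistent with printed NE/ME ratios",
    "IDF correlation row inconsistent with the printed IDF compositions",
    "composition CVs follow no single sd convention across analytes",
    "RMSE of the CP-only and GE+CP equations appear interchanged in print")
  out
}
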