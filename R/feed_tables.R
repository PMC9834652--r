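## Ingredient composition and diet formulation tables: validation, derived
## chemistry (SDF = TDF - IDF, CP = 6.25 x N) and CSV I/O.

INGREDIENT_ANALYTES <- c("GE", "DM", "CP", "EE", "starch", "NDF", "ADF",
                         "IDF", "SDF", "TDF", "ash", "N")

# CSV header -> internal column names
.ING_SCHEMA <- c(ingredient_id = "ingredient_id", GE_MJ_kgDM = "GE",
                 DM_pct = "DM", CP_pctDM = "CP", EE_pctDM = "EE",
                 starch_pctDM = "starch", NDF_pctDM = "NDF", ADF_pctDM = "ADF",
                 IDF_pctDM = "IDF", SDF_pctDM = "SDF", TDF_pctDM = "TDF",
                 ash_pctDM = "ash", N_pctDM = "N")

#' Soluble dietary fiber by difference
#'
#' Soluble dietary fiber (SDF) is the difference between total (TDF) and
#' insoluble (IDF) dietary fiber, all on a % DM basis.
#'
#' @param tdf Total dietary fiber, % DM.
#' @param idf Insoluble dietary fiber, % DM.
#' @return SDF, % DM.
#' @examples
#' derive_sdf(50.45, 46.88)
#' @export
derive_sdf <- function(tdf, idf) {
  stopifnot(is.numeric(tdf), is.numeric(idf))
  if (any(idf < 0)) stop("IDF must be nonnegative")
  if (any(idf > tdf)) stop("IDF cannot exceed TDF")
  tdf - idf
}

#' Crude protein from nitrogen
#'
#' Crude protein is calculated as nitrogen x 6.25 (% DM).
#'
#' @param n Nitrogen content, % DM.
#' @return Crude protein, % DM.
#' @examples
#' cp_from_nitrogen(3.2)
#' @export
cp_from_nitrogen <- function(n) {
  stopifnot(is.numeric(n))
  if (any(n < 0)) stop("nitrogen must be nonnegative")
  N_TO_CP * n
}

#' Validate an ingredient composition table
#'
#' Checks the invariants of an ingredient composition record: percentages in
#' \[0, 100\], positive GE, ADF <= NDF, IDF <= TDF, SDF consistent with
#' TDF - IDF, and CP consistent with 6.25 x N when nitrogen is reported.
#' Missing SDF is derived from TDF - IDF; missing CP from nitrogen. Missing
#' optional analytes stay `NA` (never silently zero).
#'
#' @param x A data.frame with columns named as in [read_ingredient_table()]
#'   output (`ingredient_id`, `GE`, `DM`, `CP`, ..., optionally `N`).
#' @param sdf_tol Tolerance on |SDF - (TDF - IDF)|, % DM.
#' @param cp_tol Tolerance on |CP - 6.25 N|, % DM.
#' @return The validated (and completed) data.frame, invisibly classed
#'   `ingredient_table`.
#' @export
validate_ingredients <- function(x, sdf_tol = 0.02, cp_tol = 0.05) {
  stopifnot(is.data.frame(x))
  if (!"N" %in% names(x)) x$N <- NA_real_
  missing_cols <- setdiff(setdiff(INGREDIENT_ANALYTES, c("N", "SDF")), names(x))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (!"SDF" %in% names(x)) x$SDF <- NA_real_
  if (anyDuplicated(x$ingredient_id))
    stop("duplicated ingredient_id")
  for (i in seq_len(nrow(x))) {
    id <- x$ingredient_id[i]
    fail <- function(rule) stop(sprintf("ingredient '%s' (row %d): %s", id, i, rule))
    if (is.na(x$CP[i]) && !is.na(x$N[i])) x$CP[i] <- cp_from_nitrogen(x$N[i])
    pct <- unlist(x[i, setdiff(INGREDIENT_ANALYTES, c("GE", "N"))])
    if (any(pct < 0 | pct > 100, na.rm = TRUE))
      fail("percentage field outside [0, 100]")
    if (is.na(x$GE[i]) || x$GE[i] <= 0) fail("GE must be > 0")
    if (!is.na(x$NDF[i]) && !is.na(x$ADF[i]) && x$ADF[i] > x$NDF[i])
      fail("ADF exceeds NDF")
    if (!is.na(x$TDF[i]) && !is.na(x$IDF[i])) {
      if (x$IDF[i] > x$TDF[i]) fail("IDF exceeds TDF")
      if (is.na(x$SDF[i])) {
        x$SDF[i] <- derive_sdf(x$TDF[i], x$IDF[i])
      } else if (abs(x$SDF[i] - (x$TDF[i] - x$IDF[i])) > sdf_tol) {
        fail(sprintf("SDF (%.2f) inconsistent with TDF - IDF (%.2f)",
                     x$SDF[i], x$TDF[i] - x$IDF[i]))
      }
    }
    if (!is.na(x$N[i]) && !is.na(x$CP[i]) &&
        abs(x$CP[i] - cp_from_nitrogen(x$N[i])) > cp_tol)
      fail(sprintf("CP (%.2f) inconsistent with 6.25 x N (%.2f)",
                   x$CP[i], cp_from_nitrogen(x$N[i])))
  }
  class(x) <- c("ingredient_table", "data.frame")
  invisible(x)
}

#' Read an ingredient composition table from CSV
#'
#' Expects the header `ingredient_id,GE_MJ_kgDM,DM_pct,CP_pctDM,EE_pctDM,
#' starch_pctDM,NDF_pctDM,ADF_pctDM,IDF_pctDM,SDF_pctDM,TDF_pctDM,ash_pctDM`
#' with an optional trailing `N_pctDM`. Each row is validated
#' ([validate_ingredients()]); SDF and CP are derived when absent.
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_ingredients
#' @return A data.frame of class `ingredient_table`, one row per ingredient,
#'   with columns `ingredient_id`, `GE` (MJ/kg DM), `DM` (% as-fed) and the
#'   remaining analytes in % DM.
#' @examples
#' path <- system.file("extdata", "wheat_ingredients.csv", package = "swineNE")
#' ing <- read_ingredient_table(path)
#' ing$NDF
#' @export
read_ingredient_table <- function(path, sdf_tol = 0.02, cp_tol = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- setdiff(names(.ING_SCHEMA), c("SDF_pctDM", "N_pctDM"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  keep <- intersect(names(.ING_SCHEMA), names(raw))
  x <- raw[keep]
  names(x) <- .ING_SCHEMA[keep]
  for (col in setdiff(names(x), "ingredient_id")) x[[col]] <- as.numeric(x[[col]])
  if (nrow(x) == 0) {
    class(x) <- c("ingredient_table", "data.frame")
    return(x)
  }
  out <- validate_ingredients(x, sdf_tol = sdf_tol, cp_tol = cp_tol)
  attr(out, "row.names") <- seq_len(nrow(out))
  out
}

#' Write an ingredient composition table to CSV
#'
#' Inverse of [read_ingredient_table()]: writes the documented schema so that
#' a read/write round trip is the identity on validated records.
#'
#' @param x An `ingredient_table` (or compatible data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ingredient_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x[.ING_SCHEMA]
  names(out) <- names(.ING_SCHEMA)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize compositions across ingredients
#'
#' Per-analyte arithmetic mean and coefficient of variation (CV, %) across a
#' set of ingredients, as reported in composition survey tables. The CV
#' denominator convention is configurable: `"population"` divides the sum of
#' squared deviations by n (the convention matching the packaged reference
#' table), `"sample"` by n - 1.
#'
#' @param x An `ingredient_table` or data.frame of compositions.
#' @param analytes Character vector of analyte columns to summarize.
#' @param cv_denominator `"population"` (default) or `"sample"`.
#' @return A data.frame with columns `analyte`, `mean`, `cv` (%).
#' @examples
#' ing <- wheat_bran_study()$ingredients
#' summarize_compositions(ing[1:6, ], c("CP", "NDF"))
#' @export
summarize_compositions <- function(x, analytes = setdiff(INGREDIENT_ANALYTES, "N"),
                                   cv_denominator = c("population", "sample")) {
  cv_denominator <- match.arg(cv_denominator)
  stopifnot(is.data.frame(x))
  if (nrow(x) < 2) stop("need at least 2 records to summarize")
  analytes <- intersect(analytes, names(x))
  res <- lapply(analytes, function(a) {
    v <- x[[a]]
    v <- v[!is.na(v)]
    m <- mean(v)
    s <- if (cv_denominator == "population")
      sqrt(mean((v - m)^2)) else stats::sd(v)
    data.frame(analyte = a, mean = m, cv = 100 * s / m)
  })
  do.call(rbind, res)
}

#' Read diet formulation and analyzed chemistry tables
#'
#' Diet formulations come in long form (`diet_id,ingredient_id,
#' inclusion_pct_asfed,is_mixture_component,is_test_ingredient`) with a
#' companion analyzed-chemistry table (`diet_id,GE_MJ_kgDM,DM_pct,CP_pctDM,
#' EE_pctDM,NDF_pctDM,ADF_pctDM,ash_pctDM`). Inclusions must sum to
#' 100 +/- 0.01 % as-fed per diet; the reference-mixture fraction (corn,
#' soybean meal, crystalline amino acids) must be positive. A diet with no
#' test ingredient is the basal diet.
#'
#' @param diets_path Path to the long-form formulation CSV.
#' @param chemistry_path Path to the analyzed chemistry CSV.
#' @return An object of class `diet_table`: a list with data.frames
#'   `inclusions` and `chemistry`.
#' @examples
#' d <- read_diet_tables(
#'   system.file("extdata", "wheat_diets.csv", package = "swineNE"),
#'   system.file("extdata", "wheat_diet_chemistry.csv", package = "swineNE"))
#' diet_mixture_fraction(d, "WB1")
#' @export
read_diet_tables <- function(diets_path, chemistry_path) {
  for (p in c(diets_path, chemistry_path))
    if (!file.exists(p)) stop("file not found: ", p)
  inc <- utils::read.csv(diets_path, stringsAsFactors = FALSE)
  need <- c("diet_id", "ingredient_id", "inclusion_pct_asfed",
            "is_mixture_component", "is_test_ingredient")
  missing_cols <- setdiff(need, names(inc))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  inc$is_mixture_component <- as.logical(inc$is_mixture_component)
  inc$is_test_ingredient <- as.logical(inc$is_test_ingredient)
  chem_raw <- utils::read.csv(chemistry_path, stringsAsFactors = FALSE)
  schema <- c(diet_id = "diet_id", GE_MJ_kgDM = "GE", DM_pct = "DM",
              CP_pctDM = "CP", EE_pctDM = "EE", NDF_pctDM = "NDF",
              ADF_pctDM = "ADF", ash_pctDM = "ash")
  missing_cols <- setdiff(names(schema), names(chem_raw))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  chem <- chem_raw[names(schema)]
  names(chem) <- schema
  for (d in unique(inc$diet_id)) {
    rows <- inc[inc$diet_id == d, ]
    tot <- sum(rows$inclusion_pct_asfed)
    if (abs(tot - 100) > 0.01)
      stop(sprintf("diet '%s': inclusions sum to %.3f, not 100", d, tot))
    f_mix <- sum(rows$inclusion_pct_asfed[rows$is_mixture_component])
    if (f_mix <= 0)
      stop(sprintf("diet '%s': mixture fraction must be positive", d))
    if (sum(rows$is_test_ingredient) > 1)
      stop(sprintf("diet '%s': more than one test ingredient", d))
    if (!d %in% chem$diet_id)
      stop(sprintf("diet '%s' has no analyzed chemistry", d))
  }
  structure(list(inclusions = inc, chemistry = chem), class = "diet_table")
}

#' @export
print.diet_table <- function(x, ...) {
  cat("Diet table:", length(unique(x$inclusions$diet_id)), "diets,",
      length(unique(x$inclusions$ingredient_id)), "ingredients\n")
  invisible(x)
}

#' Mixture and test-ingredient inclusion fractions of a diet
#'
#' As-fed proportions (0-1 scale) of the reference basal mixture and of the
#' test ingredient in one diet.
#'
#' @param diets A `diet_table`.
#' @param diet_id Diet identifier.
#' @return List with `f_mix`, `f_test` (proportions as-fed) and `test_id`
#'   (`NA` for the basal diet).
#' @export
diet_mixture_fraction <- function(diets, diet_id) {
  rows <- diets$inclusions[diets$inclusions$diet_id == diet_id, ]
  if (nrow(rows) == 0) stop("unknown diet: ", diet_id)
  test <- rows[rows$is_test_ingredient, ]
  list(f_mix = sum(rows$inclusion_pct_asfed[rows$is_mixture_component]) / 100,
       f_test = if (nrow(test)) test$inclusion_pct_asfed / 100 else 0,
       test_id = if (nrow(test)) test$ingredient_id else NA_character_)
}
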