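## Composition-based NE prediction: Noblet-type equations and their
## relative-error validation, Pearson correlation screens, and simple /
## stepwise least-squares regression with R2, RMSE, AIC, BIC.

#' Predicted net energy from DE and proximate chemistry (Noblet equation)
#'
#' NE1 (MJ/kg DM) = 0.700 DE + (16.1 EE + 4.8 starch - 9.1 CP - 8.7 ADF)
#' x 4.184 / 1000, with DE in MJ/kg DM and chemistry in % DM (the bracket is
#' in kcal and is converted to MJ).
#'
#' @param de Digestible energy, MJ/kg DM.
#' @param ee Ether extract, % DM.
#' @param starch Starch, % DM.
#' @param cp Crude protein, % DM.
#' @param adf Acid detergent fiber, % DM.
#' @return Predicted NE, MJ/kg DM.
#' @examples
#' noblet_ne1(10.71, 2.13, 12.81, 17.32, 14.47)
#' @export
noblet_ne1 <- function(de, ee, starch, cp, adf) {
  0.700 * de + (16.1 * ee + 4.8 * starch - 9.1 * cp - 8.7 * adf) * 4.184 / 1000
}

#' Predicted net energy from ME and proximate chemistry (Noblet equation)
#'
#' NE2 (MJ/kg DM) = 0.726 ME + (13.3 EE + 3.9 starch - 6.2 CP - 8.3 ADF)
#' x 4.184 / 1000.
#'
#' @param me Metabolizable energy, MJ/kg DM.
#' @inheritParams noblet_ne1
#' @return Predicted NE, MJ/kg DM.
#' @examples
#' noblet_ne2(9.96, 2.13, 12.81, 17.32, 14.47)
#' @export
noblet_ne2 <- function(me, ee, starch, cp, adf) {
  0.726 * me + (13.3 * ee + 3.9 * starch - 6.2 * cp - 8.3 * adf) * 4.184 / 1000
}

#' Relative error of a determined NE versus the mean predicted NE
#'
#' 100 x (determined - mean(NE1, NE2)) / mean(NE1, NE2), the validation
#' statistic for calorimetry-determined NE against the two prediction
#' equations.
#'
#' @param determined Determined NE, MJ/kg DM.
#' @param ne1,ne2 Predicted NE from [noblet_ne1()] and [noblet_ne2()].
#' @return Relative error, %.
#' @examples
#' relative_error(12.47, 10.56, 10.35)
#' @export
relative_error <- function(determined, ne1, ne2) {
  pred <- (ne1 + ne2) / 2
  if (any(pred <= 0)) stop("mean predicted NE must be positive")
  100 * (determined - pred) / pred
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations between chemistry and energy variables,
#' with two-sided p-values from the t transform (as in `cor.test`).
#' Zero-variance columns are reported as `NA` with a warning.
#'
#' @param data Data.frame; rows are samples (ingredients), columns are
#'   numeric variables. No missing cells are allowed.
#' @param vars Columns to use; default all numeric columns.
#' @return An object of class `correlation_matrix`: list with matrices `r`
#'   and `p` and the sample size `n`.
#' @examples
#' study <- wheat_bran_study()
#' brans <- merge(study$ingredients, study$ingredient_energy)[1:6, ]
#' cm <- pearson_matrix(brans, c("CP", "NDF", "NE"))
#' round(cm$r, 2)
#' @export
pearson_matrix <- function(data, vars = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- as.matrix(data[vars])
  if (anyNA(x)) stop("missing cells are not allowed")
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples")
  constant <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(constant))
    warning("zero-variance column(s): ", paste(vars[constant], collapse = ", "))
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else if (!constant[i] && !constant[j]) {
        ct <- stats::cor.test(x[, i], x[, j], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlations (n =", x$n, ")\n")
  print(round(x$r, digits))
  invisible(x)
}

.model_stats <- function(fit, n_pred) {
  n <- length(stats::fitted(fit))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((stats::model.response(stats::model.frame(fit)) -
                mean(stats::model.response(stats::model.frame(fit))))^2)
  k <- n_pred + 1  # parameters including intercept
  list(r.squared = 1 - sse / sst,
       rmse = sqrt(sse / (n - k)),
       aic = n * log(sse / n) + 2 * k,
       bic = n * log(sse / n) + k * log(n),
       n = n, sse = sse)
}

#' Least-squares regression with fit statistics
#'
#' Ordinary least squares of a response on one or more predictors, reported
#' with R2, RMSE = sqrt(SSE / (n - p - 1)), AIC = n ln(SSE/n) + 2k and
#' BIC = n ln(SSE/n) + k ln(n) (Gaussian log-likelihood form, k parameters
#' including the intercept), and the overall F-test p-value.
#'
#' @param data Data.frame holding response and predictors (energies in
#'   MJ/kg DM, chemistry in % DM).
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.
#' @return An object of class `ne_regression`: list with `coefficients`
#'   (named, intercept first), `response`, `predictors`, `r.squared`,
#'   `rmse`, `aic`, `bic`, `p.value`, `n` and the underlying `fit`.
#' @examples
#' study <- wheat_bran_study()
#' brans <- merge(study$ingredients, study$ingredient_energy)[1:6, ]
#' ols_fit(brans, "NE", "CP")
#' @export
ols_fit <- function(data, response, predictors) {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0)
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  n <- nrow(data)
  if (n <= length(predictors) + 1)
    stop("need more observations than parameters")
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = data)
  if (fit$rank < length(predictors) + 1) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("collinear predictors: ", paste(aliased, collapse = ", "))
  }
  st <- .model_stats(fit, length(predictors))
  fstat <- summary(fit)$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(c(list(coefficients = stats::coef(fit), response = response,
                   predictors = predictors, p.value = pval, fit = fit),
              st[c("r.squared", "rmse", "aic", "bic", "n")]),
            class = "ne_regression")
}

#' @export
print.ne_regression <- function(x, ...) {
  co <- x$coefficients
  terms <- sprintf("%+.2f x %s", co[-1], x$predictors)
  cat(sprintf("%s = %.2f %s\n", x$response, co[1], paste(terms, collapse = " ")))
  cat(sprintf("  R2 = %.2f, RMSE = %.2f, AIC = %.2f, BIC = %.2f, p = %.4g, n = %d\n",
              x$r.squared, x$rmse, x$aic, x$bic, x$p.value, x$n))
  invisible(x)
}

# Variance inflation factors of the predictors in a design
.vif <- function(data, predictors) {
  if (length(predictors) < 2) return(stats::setNames(rep(1, length(predictors)),
                                                     predictors))
  vapply(predictors, function(v) {
    r2 <- ols_fit(data, v, setdiff(predictors, v))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise selection of NE prediction equations
#'
#' Forward selection with a backward check: at each step the candidate with
#' the smallest partial-F p-value below `entry_alpha` is added, provided it
#' does not push any variance-inflation factor above `collinearity_limit`;
#' after each addition, terms whose p-value has risen above `stay_alpha` are
#' dropped (largest first). All models visited along the path are returned,
#' ranked by R2 (descending), then RMSE (ascending), then fewer parameters,
#' then alphabetical predictor names. The defaults 0.15/0.15 are the
#' conventional stepwise entry/stay levels for small-n feed evaluation
#' datasets; with n = 6 a second predictor can rarely clear 0.05.
#'
#' @inheritParams ols_fit
#' @param candidates Character vector of candidate predictor columns.
#' @param entry_alpha Significance level to enter, default 0.15.
#' @param stay_alpha Significance level to stay, default 0.15.
#' @param collinearity_limit Maximum admissible VIF, default 10.
#' @return A list of `ne_regression` models (possibly empty, with a
#'   diagnostic message when no candidate passes entry).
#' @examples
#' study <- wheat_bran_study()
#' brans <- merge(study$ingredients, study$ingredient_energy)[1:6, ]
#' mods <- stepwise_select(brans, "NE", c("GE", "ME"))
#' mods[[1]]
#' @export
stepwise_select <- function(data, response, candidates,
                            entry_alpha = 0.15, stay_alpha = 0.15,
                            collinearity_limit = 10) {
  stopifnot(length(candidates) >= 1, nrow(data) > 2)
  current <- character(0)
  visited <- list()
  repeat {
    pool <- setdiff(candidates, current)
    if (length(pool) == 0) break
    # partial-F p-value of each addition = t-test p of its coefficient
    entry <- vapply(sort(pool), function(v) {
      trial <- c(current, v)
      if (any(.vif(data, trial) > collinearity_limit)) return(NA_real_)
      fit <- ols_fit(data, response, trial)$fit
      stats::coef(summary(fit))[v, "Pr(>|t|)"]
    }, numeric(1))
    entry <- entry[!is.na(entry) & entry < entry_alpha]
    if (length(entry) == 0) break
    current <- c(current, names(which.min(entry)))
    # backward check
    repeat {
      fit <- ols_fit(data, response, current)$fit
      pv <- stats::coef(summary(fit))[current, "Pr(>|t|)", drop = TRUE]
      if (all(pv <= stay_alpha)) break
      current <- setdiff(current, names(which.max(pv)))
      if (length(current) == 0) break
    }
    if (length(current) == 0) break
    visited[[paste(sort(current), collapse = "+")]] <-
      ols_fit(data, response, current)
    if (length(current) == length(candidates)) break
  }
  if (length(visited) == 0) {
    message("no candidate predictor passed the entry threshold (alpha = ",
            entry_alpha, ")")
    return(list())
  }
  ord <- order(-vapply(visited, `[[`, numeric(1), "r.squared"),
               vapply(visited, `[[`, numeric(1), "rmse"),
               vapply(visited, function(m) length(m$predictors), integer(1)),
               vapply(visited, function(m)
                 paste(sort(m$predictors), collapse = "+"), character(1)))
  unname(visited[ord])
}

#' Noblet prediction validation table
#'
#' For each ingredient with determined DE/ME/NE and chemistry, computes the
#' two predicted NE values and the relative error of the determined NE
#' against their mean.
#'
#' @param energy Data.frame with `ingredient_id`, determined `DE`, `ME`,
#'   `NE` (MJ/kg DM).
#' @param chemistry Data.frame with `ingredient_id`, `EE`, `starch`, `CP`,
#'   `ADF` (% DM).
#' @return Data.frame with `ingredient_id, predicted_NE1, predicted_NE2,
#'   relative_error`.
#' @export
noblet_validation <- function(energy, chemistry) {
  m <- merge(energy, chemistry, by = "ingredient_id", suffixes = c("", ".chem"))
  ne1 <- noblet_ne1(m$DE, m$EE, m$starch, m$CP, m$ADF)
  ne2 <- noblet_ne2(m$ME, m$EE, m$starch, m$CP, m$ADF)
  data.frame(ingredient_id = m$ingredient_id,
             predicted_NE1 = ne1, predicted_NE2 = ne2,
             relative_error = relative_error(m$NE, ne1, ne2))
}
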