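#' Total symptom severity score
#'
#' Row sum of the item severity ratings: with p items on the 1-5 scale
#' the score ranges from p to 5p.
#'
#' @param table A [symptom_table()].
#' @return Numeric vector of per-person scores.
#' @export
total_severity <- function(table) {
  rowSums(ratings_matrix(table))
}

#' Covariate-screening regression of total symptom severity
#'
#' Multivariable linear regression of the total severity score on
#' person-level predictors; the screening stage that decides which
#' covariates enter the adjusted network. Reports unstandardized
#' coefficients B, standardized coefficients beta (B scaled by
#' sd(x)/sd(y)), two-sided p-values, 95% confidence intervals, and
#' per-predictor variance inflation factors, plus residual diagnostics
#' (scale-location slope test for homoscedasticity/linearity, a
#' Shapiro-Wilk residual normality test, and a max-VIF multicollinearity
#' flag). Diagnostics are reported as flags, never as hard failures.
#'
#' @param table A [symptom_table()].
#' @param predictors Character vector of predictor columns (defaults to
#'   the table's covariates).
#' @param conf_level Confidence level for the intervals.
#' @param vif_flag_limit Max VIF above which the multicollinearity flag
#'   is raised.
#' @return An object of class `severity_fit` with `coefficients` (a
#'   tibble: `term`, `B`, `beta`, `p_value`, `conf_low`, `conf_high`,
#'   `vif`), `r_squared`, `diagnostics`, and the underlying `model`.
#' @export
fit_severity_model <- function(table, predictors = symptom_covariates(table),
                               conf_level = 0.95, vif_flag_limit = 10) {
  if (length(predictors) == 0) {
    abort("no predictors supplied", class = "symptomnet_domain_error")
  }
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("predictors not in table: ",
                 paste(missing_cols, collapse = ", ")),
          class = "symptomnet_schema_error")
  }
  y <- total_severity(table)
  X <- as.matrix(table[, predictors, drop = FALSE])
  qr_x <- qr(cbind(`(Intercept)` = 1, X))
  if (qr_x$rank < ncol(X) + 1) {
    aliased <- colnames(qr_x$qr)[qr_x$pivot[seq.int(qr_x$rank + 1,
                                                    ncol(X) + 1)]]
    abort(paste0("rank-deficient design; aliased column(s): ",
                 paste(aliased, collapse = ", ")),
          class = "symptomnet_domain_error")
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", predictors), response = ".y")
  model <- lm(fml, data = df)
  sm <- summary(model)
  ci <- stats::confint(model, level = conf_level)
  B <- coef(model)[predictors]
  beta <- B * apply(X, 2, sd) / sd(y)
  vif <- if (length(predictors) >= 2) {
    v <- car::vif(model)
    as.numeric(v)[match(predictors, names(v))]
  } else {
    1
  }
  coefs <- tibble::tibble(
    term = predictors,
    B = as.numeric(B),
    beta = as.numeric(beta),
    p_value = sm$coefficients[predictors, "Pr(>|t|)"],
    conf_low = ci[predictors, 1],
    conf_high = ci[predictors, 2],
    vif = vif
  )
  res <- residuals(model)
  fit_vals <- fitted(model)
  # scale-location proxy: slope of |residual| on fitted values
  sl <- summary(lm(abs(res) ~ fit_vals))$coefficients
  sl_p <- if (nrow(sl) > 1) sl[2, 4] else NA_real_
  norm_p <- if (length(res) >= 3 && length(res) <= 5000) {
    shapiro.test(res)$p.value
  } else {
    NA_real_
  }
  diagnostics <- list(
    scale_location_p = sl_p,
    heteroscedastic_flag = !is.na(sl_p) && sl_p < 0.05,
    normality_p = norm_p,
    nonnormal_flag = !is.na(norm_p) && norm_p < 0.05,
    max_vif = max(coefs$vif),
    multicollinearity_flag = max(coefs$vif) > vif_flag_limit
  )
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 diagnostics = diagnostics, n = nrow(table),
                 conf_level = conf_level, model = model),
            class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat("<severity_fit> n = ", x$n, ", R^2 = ", signif(x$r_squared, 4),
      "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_severity_model
#' @param x A `severity_fit`.
#' @param ... Unused.
#' @export
tidy.severity_fit <- function(x, ...) x$coefficients

#' @rdname fit_severity_model
#' @export
glance.severity_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n, max_vif = x$diagnostics$max_vif,
                 heteroscedastic_flag = x$diagnostics$heteroscedastic_flag,
                 nonnormal_flag = x$diagnostics$nonnormal_flag)
}

#' Screen covariates by regression significance
#'
#' Returns the predictors whose two-sided p-value falls below the
#' screening level; these are the covariates carried into the adjusted
#' network. A stringent default of 0.001 suppresses false-positive
#' covariates.
#'
#' @param fit A [fit_severity_model()] result.
#' @param alpha_screen Significance level for selection.
#' @return Character vector of selected predictor names with attribute
#'   `alpha_screen`.
#' @export
screen_covariates <- function(fit, alpha_screen = 0.001) {
  stopifnot(inherits(fit, "severity_fit"))
  sel <- fit$coefficients$term[fit$coefficients$p_value < alpha_screen]
  attr(sel, "alpha_screen") <- alpha_screen
  sel
}

#' Post hoc power of a multiple-regression F test
#'
#' Power of the overall F test of a linear model with `u` predictors at
#' effect size f-squared and sample size N: the probability that a
#' noncentral F variate with noncentrality `f2 * N` and degrees of
#' freedom (u, N - u - 1) exceeds the central-F critical value at level
#' alpha (the fixed-model "R-squared deviation from zero" convention).
#'
#' @param u Number of predictors.
#' @param f2 Cohen's f-squared effect size (>= 0).
#' @param alpha Test level in (0, 1).
#' @param N Total sample size (must exceed u + 1).
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_f_test(u = 13, f2 = 0.15, alpha = 0.001, N = 324) # ~0.98
power_f_test <- function(u, f2, alpha, N) {
  if (N <= u + 1) abort("need N > u + 1", class = "symptomnet_domain_error")
  if (f2 < 0 || alpha <= 0 || alpha >= 1) {
    abort("need f2 >= 0 and alpha in (0,1)",
          class = "symptomnet_domain_error")
  }
  df2 <- N - u - 1
  fcrit <- qf(1 - alpha, u, df2)
  1 - pf(fcrit, u, df2, ncp = f2 * N)
}
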