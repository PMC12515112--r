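# Step 3: weighted linear mixed models on the stacked per-population
# coefficients of survival and productivity.
#
# Model A: coefficient ~ measure, random intercepts for scheme and species.
# Model B: coefficient ~ measure * mean_temp, random intercept for species
#          (temperature is already scheme-specific).
# Model C: coefficient ~ measure * migration + measure * habitat, random
#          intercepts for scheme and species.
# All models weight each row by 1 / SE^2 (inverse-variance weighting with a
# freely estimated common residual scale).

MEASURE_LEVELS <- c("productivity", "survival")
MIGRATION_LEVELS <- c("long-distance", "short/resident")
HABITAT_LEVELS <- c("forest", "reed")

#' Stack per-population coefficients with traits and temperature
#'
#' Builds the long-format meta-analysis table: one row per (scheme, species,
#' measure) holding the step-2 coefficient and its SE together with the
#' scheme mean breeding-season temperature and the species traits. Reference
#' levels are productivity (measure), long-distance (migration) and forest
#' (habitat).
#'
#' @param growth `growth_coefficients` rows (one per population), as returned
#'   by [fit_growth_lm()] and combined with `rbind`.
#' @param traits data frame with `species`, `migration`
#'   (`"long-distance"`/`"short/resident"`) and `habitat`
#'   (`"forest"`/`"reed"`).
#' @param temperatures data frame with `scheme` and `mean_temp_c`.
#' @return An object of class `meta_table`.
#' @export
stack_coefficients <- function(growth, traits, temperatures) {
  long <- growth_long(growth)
  miss_sp <- setdiff(unique(long$species), traits$species)
  if (length(miss_sp) > 0) {
    stop("missing trait entry for species: ", paste(miss_sp, collapse = ", "))
  }
  miss_sc <- setdiff(unique(long$scheme), temperatures$scheme)
  if (length(miss_sc) > 0) {
    stop("missing temperature entry for scheme: ",
         paste(miss_sc, collapse = ", "))
  }
  it <- match(long$species, traits$species)
  is <- match(long$scheme, temperatures$scheme)
  out <- data.frame(
    scheme = long$scheme, species = long$species,
    measure = factor(long$measure, levels = MEASURE_LEVELS),
    coefficient = long$coefficient, se = long$se,
    mean_temp_c = temperatures$mean_temp_c[is],
    migration = factor(traits$migration[it], levels = MIGRATION_LEVELS),
    habitat = factor(traits$habitat[it], levels = HABITAT_LEVELS),
    stringsAsFactors = FALSE)
  if (any(is.na(out$migration)) || any(is.na(out$habitat))) {
    stop("trait values must be in the documented two-level codings")
  }
  if (any(!is.finite(out$se)) || any(out$se <= 0)) {
    stop("all coefficient SEs must be positive")
  }
  rownames(out) <- NULL
  structure(out, class = c("meta_table", "data.frame"))
}

meta_formula <- function(model) {
  switch(model,
         A = coefficient ~ measure + (1 | scheme) + (1 | species),
         B = coefficient ~ measure * mean_temp_c + (1 | species),
         C = coefficient ~ measure * migration + measure * habitat +
           (1 | scheme) + (1 | species),
         stop("model must be one of 'A', 'B', 'C'"))
}

#' Fit one of the three weighted linear mixed meta-models
#'
#' Gaussian LMM fitted by REML (via \pkg{lme4}/\pkg{lmerTest}) where row `k`
#' has residual variance `sigma^2 / w_k` with `w_k = 1 / SE_k^2`; t-tests on
#' the fixed effects use Satterthwaite degrees of freedom.
#'
#' @param table a [stack_coefficients()] result.
#' @param model `"A"` (measure), `"B"` (measure x temperature) or `"C"`
#'   (measure x migration + measure x habitat).
#' @param reml fit by REML (default) or ML.
#' @return An object of class `meta_fit`: list with `model`, `coefficients`
#'   (parameter, estimate, se, df, t, p), `varcor` (random-effect standard
#'   deviations), `sigma`, `logLik`, `singular` flag and the underlying
#'   `lmerModLmerTest` fit.
#' @export
fit_weighted_lmm <- function(table, model = c("A", "B", "C"), reml = TRUE) {
  model <- match.arg(model)
  d <- as.data.frame(table)
  d$w <- 1 / d$se^2
  fit <- lmerTest::lmer(meta_formula(model), data = d, weights = w,
                        REML = reml,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular fit: a random-effect variance is estimated at zero")
  }
  co <- summary(fit)$coefficients
  coef_df <- data.frame(parameter = rownames(co),
                        estimate = co[, "Estimate"],
                        se = co[, "Std. Error"],
                        df = co[, "df"], t = co[, "t value"],
                        p = co[, "Pr(>|t|)"],
                        stringsAsFactors = FALSE)
  rownames(coef_df) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = model, coefficients = coef_df,
                 varcor = vc, sigma = stats::sigma(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 singular = singular, fit = fit),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("<meta_fit> model ", x$model, " (weighted LMM, ",
      if (x$singular) "singular, " else "", "logLik = ",
      format(x$logLik, digits = 6), ")\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Predicted coefficient curves over a temperature gradient (model B)
#'
#' Fixed-effect linear predictions, with pointwise delta-method SEs, of the
#' demographic coefficient over a grid of scheme mean temperatures, for each
#' demographic measure. Warns when the grid extends beyond the temperature
#' range seen by the fit.
#'
#' @param fit a model-B [fit_weighted_lmm()] result.
#' @param temp_grid numeric vector of temperatures (degrees C).
#' @return data frame with `measure`, `mean_temp_c`, `predicted`, `se`.
#' @export
temperature_gradient_prediction <- function(fit, temp_grid) {
  stopifnot(inherits(fit, "meta_fit"))
  if (fit$model != "B") stop("temperature predictions require model B")
  obs <- stats::model.frame(fit$fit)$mean_temp_c
  if (any(temp_grid < min(obs)) || any(temp_grid > max(obs))) {
    warning("temperature grid extends beyond the observed range [",
            format(min(obs)), ", ", format(max(obs)), "]")
  }
  beta <- lme4::fixef(fit$fit)
  V <- as.matrix(stats::vcov(fit$fit))
  out <- NULL
  for (m in MEASURE_LEVELS) {
    is_surv <- as.numeric(m == "survival")
    X <- cbind(1, is_surv, temp_grid, is_surv * temp_grid)
    colnames(X) <- c("(Intercept)", "measuresurvival", "mean_temp_c",
                     "measuresurvival:mean_temp_c")
    X <- X[, names(beta), drop = FALSE]
    pred <- drop(X %*% beta)
    se <- sqrt(rowSums((X %*% V) * X))
    out <- rbind(out, data.frame(measure = m, mean_temp_c = temp_grid,
                                 predicted = pred, se = se,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
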