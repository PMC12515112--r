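# Step 2: annual growth rates and the per-population weighted regression of
# growth on z-scaled survival and productivity.

#' Annual population growth rate
#'
#' `r = log(1 + (x_next - x) / x)`, i.e. the log ratio of successive annual
#' abundance indices. Vectorized; both arguments must be positive.
#'
#' @param x abundance index in year `t`.
#' @param x_next abundance index in year `t + 1`.
#' @return The growth rate(s) `log(x_next / x)`.
#' @export
growth_rate <- function(x, x_next) {
  if (any(!is.finite(x)) || any(!is.finite(x_next)) ||
      any(x <= 0) || any(x_next <= 0)) {
    stop("abundance must be positive and finite")
  }
  log(1 + (x_next - x) / x)
}

#' Scale a numeric vector to mean zero and unit standard deviation
#'
#' Uses the sample standard deviation (n - 1 denominator). A constant series
#' has no scale and is an error.
#'
#' @param values numeric vector with at least two distinct values.
#' @return The centred and scaled vector.
#' @export
zscale <- function(values) {
  if (length(unique(values)) < 2) {
    stop("cannot z-scale a constant series: ",
         paste(utils::head(values, 3), collapse = ", "))
  }
  (values - mean(values)) / stats::sd(values)
}

#' Inverse-variance weight from the three demographic standard errors
#'
#' The weight of a year is `1 / mean(SE)^2`, the inverse square of the mean
#' of the survival, productivity and abundance standard errors. SEs must be
#' non-negative with a positive mean (the abundance reference year carries
#' SE 0 by construction).
#'
#' @param se_phi,se_rho,se_x standard errors of the survival, productivity
#'   and abundance estimates (vectorized).
#' @return The weight(s) `1 / ((se_phi + se_rho + se_x) / 3)^2`.
#' @export
combine_step2_weights <- function(se_phi, se_rho, se_x) {
  se <- cbind(se_phi, se_rho, se_x)
  if (any(!is.finite(se)) || any(se < 0)) {
    stop("standard errors must be finite and non-negative")
  }
  m <- rowMeans(se)
  if (any(m <= 0)) stop("mean standard error must be positive")
  as.vector(1 / m^2)
}

#' Assemble the aligned demographic series for one population
#'
#' Pairs growth over the interval `t -> t+1` with survival over the same
#' interval and productivity of year `t`; the abundance SE entering the
#' weight is that of the start of the interval. Only intervals whose start
#' year passed the survival-SE filter and whose two endpoint years both carry
#' an abundance index are used.
#'
#' @param cjs a [fit_cjs_transient()] result.
#' @param retained_years interval start years retained by
#'   [filter_by_survival_se()].
#' @param productivity,abundance `index_series` from [fit_productivity_glm()]
#'   and [fit_abundance_glm()].
#' @return An object of class `demographic_series`: one row per usable
#'   year-pair with `year`, `phi`, `se_phi`, `rho`, `se_rho`, `x`, `se_x`,
#'   `x_next`.
#' @export
build_demographic_series <- function(cjs, retained_years, productivity,
                                     abundance) {
  stopifnot(inherits(cjs, "cjs_fit"),
            inherits(productivity, "index_series"),
            inherits(abundance, "index_series"))
  phi <- cjs$phi
  pe <- productivity$estimates
  ae <- abundance$estimates
  rows <- NULL
  for (i in seq_len(nrow(phi))) {
    t0 <- phi$year_start[i]
    t1 <- phi$year_end[i]
    if (!(t0 %in% retained_years)) next
    ip <- match(t0, pe$year)
    ia0 <- match(t0, ae$year)
    ia1 <- match(t1, ae$year)
    if (is.na(ip) || is.na(ia0) || is.na(ia1)) next
    if (pe$flagged[ip] || ae$flagged[ia0] || ae$flagged[ia1]) next
    rows <- rbind(rows, data.frame(
      year = t0, phi = phi$estimate[i], se_phi = phi$se[i],
      rho = pe$estimate[ip], se_rho = pe$se[ip],
      x = ae$estimate[ia0], se_x = ae$se[ia0],
      x_next = ae$estimate[ia1]))
  }
  if (is.null(rows)) rows <- data.frame(year = integer(), phi = numeric(),
                                        se_phi = numeric(), rho = numeric(),
                                        se_rho = numeric(), x = numeric(),
                                        se_x = numeric(), x_next = numeric())
  structure(rows, class = c("demographic_series", "data.frame"),
            species = cjs$species, scheme = cjs$scheme)
}

#' Per-population weighted regression of growth on survival and productivity
#'
#' Weighted least squares of the annual growth rate on the z-scaled survival
#' and productivity series (scaling is within the population), with an
#' intercept and yearly weights `1 / mean(SE)^2` from
#' [combine_step2_weights()].
#'
#' @param series a [build_demographic_series()] result (or any data frame
#'   with the same columns).
#' @param min_pairs minimum number of aligned year-pairs (default 4, so that
#'   slope SEs exist with at least one residual degree of freedom).
#' @return An object of class `growth_coefficients`: one-row data frame with
#'   `scheme`, `species`, `beta_survival`, `se_survival`,
#'   `beta_productivity`, `se_productivity`, `n_years`, `r_squared`.
#' @export
fit_growth_lm <- function(series, min_pairs = 4) {
  d <- as.data.frame(series)
  if (nrow(d) < min_pairs) {
    stop("population dropped: only ", nrow(d), " usable year-pairs (need ",
         min_pairs, ")")
  }
  z_phi <- zscale(d$phi)
  z_rho <- zscale(d$rho)
  if (abs(stats::cor(z_phi, z_rho)) >= 1 - 1e-12) {
    stop("survival and productivity predictors are perfectly collinear")
  }
  r <- growth_rate(d$x, d$x_next)
  w <- combine_step2_weights(d$se_phi, d$se_rho, d$se_x)
  fit <- stats::lm(r ~ z_phi + z_rho, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(
    scheme = attr(series, "scheme") %||% NA_character_,
    species = attr(series, "species") %||% NA_character_,
    beta_survival = co["z_phi", "Estimate"],
    se_survival = co["z_phi", "Std. Error"],
    beta_productivity = co["z_rho", "Estimate"],
    se_productivity = co["z_rho", "Std. Error"],
    n_years = nrow(d), r_squared = sm$r.squared,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("growth_coefficients", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format view of growth coefficients for the meta-models
#'
#' @param growth a `growth_coefficients` data frame (one or more rows).
#' @return data frame with one row per (scheme, species, measure):
#'   `measure` in `{productivity, survival}`, `coefficient`, `se`, `n_years`.
#' @export
growth_long <- function(growth) {
  g <- as.data.frame(growth)
  long <- rbind(
    data.frame(scheme = g$scheme, species = g$species,
               measure = "survival", coefficient = g$beta_survival,
               se = g$se_survival, n_years = g$n_years,
               stringsAsFactors = FALSE),
    data.frame(scheme = g$scheme, species = g$species,
               measure = "productivity", coefficient = g$beta_productivity,
               se = g$se_productivity, n_years = g$n_years,
               stringsAsFactors = FALSE))
  long[order(long$scheme, long$species, long$measure), , drop = FALSE]
}
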