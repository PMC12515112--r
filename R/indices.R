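# Annual productivity and adult-abundance indices via quasi-likelihood GLMs
# with categorical site and year effects.

#' Tabulate distinct individuals per site-year by age class
#'
#' @param table a [capture_table()] (after selection filtering).
#' @param species species code.
#' @param scheme scheme code.
#' @return An object of class `site_year_counts`: data frame with `site`,
#'   `year`, `adults`, `juveniles` (distinct individuals), for every
#'   site-year at which the species has records.
#' @export
tabulate_counts <- function(table, species, scheme) {
  df <- as.data.frame(table)
  df <- df[df$scheme == scheme & df$species == species, , drop = FALSE]
  if (nrow(df) == 0) stop("no records for ", species, " in scheme ", scheme)
  key <- paste(df$site, df$year, sep = "\r")
  u <- !duplicated(key)
  out <- data.frame(site = df$site[u], year = df$year[u],
                    stringsAsFactors = FALSE)
  cnt <- function(age) {
    v <- tapply(ifelse(df$age_class == age, df$ring_id, NA), key,
                function(x) length(unique(x[!is.na(x)])))
    as.integer(v[paste(out$site, out$year, sep = "\r")])
  }
  out$adults <- cnt("A")
  out$juveniles <- cnt("J")
  out <- out[order(out$site, out$year), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("site_year_counts", "data.frame"),
            species = species, scheme = scheme)
}

# annual linear combination on the link scale: intercept + mean site effect
# + year effect; returns estimate/se per year on the response scale
annual_from_glm <- function(fit, years, dispersion, inv_link, d_inv_link) {
  cf <- stats::coef(fit)
  ok <- !is.na(cf)
  V <- stats::summary.glm(fit, dispersion = dispersion)$cov.scaled
  site_idx <- grep("^site", names(cf))
  n_sites <- length(site_idx) + 1  # + reference site
  est <- se <- numeric(length(years))
  for (i in seq_along(years)) {
    cvec <- stats::setNames(numeric(length(cf)), names(cf))
    if ("(Intercept)" %in% names(cf)) cvec["(Intercept)"] <- 1
    if (length(site_idx) > 0) cvec[site_idx] <- 1 / n_sites
    ynm <- paste0("year", years[i])
    if (ynm %in% names(cf)) cvec[ynm] <- 1
    cvec_ok <- cvec[ok]
    eta <- sum(cvec_ok * cf[ok])
    v <- drop(t(cvec_ok) %*% V %*% cvec_ok)
    est[i] <- inv_link(eta)
    se[i] <- sqrt(max(v, 0)) * abs(d_inv_link(eta))
  }
  list(estimate = est, se = se)
}

#' Annual productivity index (quasi-binomial GLM)
#'
#' Fits a logit-link binomial GLM in an event-trial framework -- each capture
#' is a trial and a capture of a juvenile is a success -- with categorical
#' site and year effects and quasi-binomial dispersion. The annual estimate
#' is the predicted juvenile proportion at the average site effect (mean of
#' site coefficients on the link scale); SEs come from the delta method with
#' the Pearson dispersion scaling the covariance.
#'
#' Years in which all captures across sites are juvenile or all adult are
#' separated on the link scale; their estimate is reported but the SE is
#' flagged unavailable.
#'
#' @param counts a [tabulate_counts()] result.
#' @return An object of class `index_series` with `kind = "productivity"`,
#'   `estimates` (year, estimate, se, flagged), `dispersion` (Pearson
#'   chi-square / residual df; `NA` when the model is saturated),
#'   `df_residual` and the fitted `glm` object.
#' @export
fit_productivity_glm <- function(counts) {
  stopifnot(inherits(counts, "site_year_counts"))
  d <- as.data.frame(counts)
  if (length(unique(d$site)) < 2 && length(unique(d$year)) < 2) {
    stop("need at least 2 sites or 2 years")
  }
  years <- sort(unique(d$year))
  d$site <- factor(d$site)
  d$year <- factor(d$year, levels = years)
  form <- if (nlevels(d$site) > 1) {
    cbind(juveniles, adults) ~ site + year
  } else {
    cbind(juveniles, adults) ~ year
  }
  fit <- stats::glm(form, family = stats::quasibinomial(), data = d)
  df_res <- stats::df.residual(fit)
  disp <- if (df_res > 0) pearson_dispersion(fit) else NA_real_
  disp_use <- if (is.finite(disp) && disp > 0) disp else 1
  ann <- annual_from_glm(fit, years, disp_use,
                         inv_link = stats::plogis,
                         d_inv_link = function(e) {
                           mu <- stats::plogis(e)
                           mu * (1 - mu)
                         })
  tot_j <- tapply(d$juveniles, d$year, sum)[as.character(years)]
  tot_a <- tapply(d$adults, d$year, sum)[as.character(years)]
  flagged <- tot_j == 0 | tot_a == 0
  se <- ann$se
  se[flagged] <- NA_real_
  structure(list(kind = "productivity",
                 species = attr(counts, "species"),
                 scheme = attr(counts, "scheme"),
                 estimates = data.frame(year = years, estimate = ann$estimate,
                                        se = se, flagged = flagged),
                 dispersion = disp, df_residual = df_res, fit = fit),
            class = "index_series")
}

#' Annual adult-abundance index (quasi-Poisson GLM)
#'
#' Models the number of distinct adults captured per site and year with a
#' log-link Poisson GLM, categorical site and year effects and quasi-Poisson
#' dispersion. The annual index is `exp(gamma_t)` with the first year as the
#' reference (`gamma_1 = 0`, so `x_1 = 1` with SE 0); SEs for later years by
#' the delta method with the quasi-dispersion. Growth rates depend only on
#' index ratios, so the reference choice is immaterial for downstream use,
#' but SEs are reference-dependent.
#'
#' @param counts a [tabulate_counts()] result (adults only are used).
#' @return An `index_series` with `kind = "abundance"`.
#' @export
fit_abundance_glm <- function(counts) {
  stopifnot(inherits(counts, "site_year_counts"))
  d <- as.data.frame(counts)
  if (length(unique(d$site)) < 2 && length(unique(d$year)) < 2) {
    stop("need at least 2 sites or 2 years")
  }
  years <- sort(unique(d$year))
  d$site <- factor(d$site)
  d$year <- factor(d$year, levels = years)
  form <- if (nlevels(d$site) > 1) adults ~ site + year else adults ~ year
  fit <- stats::glm(form, family = stats::quasipoisson(), data = d)
  df_res <- stats::df.residual(fit)
  disp <- if (df_res > 0) pearson_dispersion(fit) else NA_real_
  disp_use <- if (is.finite(disp) && disp > 0) disp else 1
  V <- stats::summary.glm(fit, dispersion = disp_use)$cov.scaled
  cf <- stats::coef(fit)
  est <- se <- numeric(length(years))
  for (i in seq_along(years)) {
    ynm <- paste0("year", years[i])
    if (ynm %in% names(cf) && !is.na(cf[ynm])) {
      g <- cf[ynm]
      vg <- V[ynm, ynm]
      est[i] <- exp(g)
      se[i] <- exp(g) * sqrt(max(vg, 0))
    } else {
      est[i] <- 1
      se[i] <- 0
    }
  }
  tot_a <- tapply(d$adults, d$year, sum)[as.character(years)]
  flagged <- tot_a == 0
  se[flagged] <- NA_real_
  structure(list(kind = "abundance",
                 species = attr(counts, "species"),
                 scheme = attr(counts, "scheme"),
                 estimates = data.frame(year = years, estimate = est,
                                        se = se, flagged = flagged),
                 dispersion = disp, df_residual = df_res, fit = fit),
            class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  cat("<index_series> ", x$kind, " ", x$species, " / ", x$scheme,
      ", dispersion = ", format(x$dispersion, digits = 3), "\n", sep = "")
  print(x$estimates, digits = 3)
  invisible(x)
}

#' Pearson dispersion statistic of a fitted GLM
#'
#' `sum((observed - fitted)^2 / variance_function(fitted)) / residual df`,
#' i.e. the Pearson chi-square divided by the residual degrees of freedom.
#'
#' @param fit a fitted [stats::glm()] object with positive residual df.
#' @return The dispersion estimate (a positive number).
#' @export
pearson_dispersion <- function(fit) {
  df_res <- stats::df.residual(fit)
  if (df_res <= 0) stop("dispersion undefined: residual df = 0")
  sum(stats::residuals(fit, type = "pearson")^2) / df_res
}

#' Dispersion-based keep/drop decision for a species
#'
#' A species is dropped from a scheme when the Pearson dispersion of either
#' index model is `>= threshold` ("under four" is strict).
#'
#' @param series an `index_series`, a list of them, or a numeric vector of
#'   dispersion values.
#' @param threshold dispersion threshold (default 4).
#' @return list with logical `keep`, the `dispersion` values examined and a
#'   `reason` string when dropped.
#' @export
filter_by_dispersion <- function(series, threshold = 4) {
  disp <- if (is.numeric(series)) {
    series
  } else if (inherits(series, "index_series")) {
    series$dispersion
  } else {
    vapply(series, function(s) s$dispersion, numeric(1))
  }
  bad <- is.finite(disp) & disp >= threshold
  list(keep = !any(bad), dispersion = disp,
       reason = if (any(bad)) {
         sprintf("dispersion %.2f >= %g", max(disp[bad]), threshold)
       } else {
         NA_character_
       })
}
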