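make_growth <- function(n_species = 6, n_schemes = 3, seed = 1) {
  set.seed(seed)
  g <- expand.grid(species = sprintf("SP%02d", seq_len(n_species)),
                   scheme = sprintf("SC%02d", seq_len(n_schemes)),
                   stringsAsFactors = FALSE)
  g$beta_survival <- rnorm(nrow(g), 0.08, 0.05)
  g$se_survival <- runif(nrow(g), 0.02, 0.1)
  g$beta_productivity <- rnorm(nrow(g), 0.06, 0.05)
  g$se_productivity <- runif(nrow(g), 0.02, 0.1)
  g$n_years <- 8
  g$r_squared <- 0.5
  structure(g, class = c("growth_coefficients", "data.frame"))
}

make_traits <- function(species) {
  data.frame(species = species,
             migration = rep(c("long-distance", "short/resident"),
                             length.out = length(species)),
             habitat = rep(c("forest", "forest", "reed"),
                           length.out = length(species)),
             stringsAsFactors = FALSE)
}

make_temps <- function(schemes) {
  data.frame(scheme = schemes,
             mean_temp_c = seq(8, 16, length.out = length(schemes)))
}

test_that("stacking yields two rows per population with reference levels", {
  g <- make_growth(6, 3)
  tab <- stack_coefficients(g, make_traits(unique(g$species)),
                            make_temps(unique(g$scheme)))
  expect_equal(nrow(tab), 2 * nrow(g))
  expect_equal(levels(tab$measure), c("productivity", "survival"))
  expect_equal(levels(tab$migration), c("long-distance", "short/resident"))
  expect_equal(levels(tab$habitat), c("forest", "reed"))
  # a dropped population contributes no placeholder rows
  g2 <- g[-1, ]
  tab2 <- stack_coefficients(g2, make_traits(unique(g$species)),
                             make_temps(unique(g$scheme)))
  expect_equal(nrow(tab2), 2 * (nrow(g) - 1))
})

test_that("missing trait or temperature entries raise named errors", {
  g <- make_growth(4, 2)
  traits <- make_traits(unique(g$species))
  temps <- make_temps(unique(g$scheme))
  expect_error(stack_coefficients(g, traits[-1, ], temps), "SP01")
  expect_error(stack_coefficients(g, traits, temps[-1, ]), "SC01")
})

test_that("with zero random-effect variance the LMM equals the WLS oracle", {
  tab <- simulate_coefficient_table(n_species = 20, n_schemes = 3,
                                    sd_species = 0, sd_scheme = 0,
                                    sd_resid = 0.05, seed = 6)
  fit <- suppressWarnings(fit_weighted_lmm(tab, "A"))
  expect_true(fit$singular)
  expect_true(all(lme4::getME(fit$fit, "theta") < 1e-8))
  X <- cbind(1, as.numeric(tab$measure == "survival"))
  beta <- oracle_wls(X, tab$coefficient, 1 / tab$se^2)
  expect_equal(fit$coefficients$estimate, as.vector(beta),
               tolerance = 1e-8)
  # and the two fixed effects are the weighted group means / their contrast
  w <- 1 / tab$se^2
  m_prod <- weighted.mean(tab$coefficient[tab$measure == "productivity"],
                          w[tab$measure == "productivity"])
  m_surv <- weighted.mean(tab$coefficient[tab$measure == "survival"],
                          w[tab$measure == "survival"])
  expect_equal(fit$coefficients$estimate[1], m_prod, tolerance = 1e-8)
  expect_equal(sum(fit$coefficients$estimate), m_surv, tolerance = 1e-8)
})

test_that("balanced duplication of all rows leaves point estimates stable", {
  tab <- simulate_coefficient_table(n_species = 15, n_schemes = 2,
                                    sd_species = 0, sd_scheme = 0,
                                    sd_resid = 0.05, seed = 8)
  dup <- rbind(tab, tab)
  class(dup) <- class(tab)
  # the inverse-variance solution itself is exactly duplication-invariant
  X <- cbind(1, as.numeric(tab$measure == "survival"))
  Xd <- rbind(X, X)
  b1 <- oracle_wls(X, tab$coefficient, 1 / tab$se^2)
  b2 <- oracle_wls(Xd, dup$coefficient, 1 / dup$se^2)
  expect_equal(b1, b2, tolerance = 1e-12)
  # the mixed model tracks it closely (REML variance components may move
  # off the boundary, but far less than an SE)
  f1 <- suppressWarnings(fit_weighted_lmm(tab, "A"))
  f2 <- suppressWarnings(fit_weighted_lmm(dup, "A"))
  expect_true(all(abs(f1$coefficients$estimate - f2$coefficients$estimate) <
                    0.2 * f1$coefficients$se))
})

test_that("switching the reference measure flips the sign of the contrast", {
  tab <- simulate_coefficient_table(n_species = 12, n_schemes = 3, seed = 9)
  f1 <- suppressWarnings(fit_weighted_lmm(tab, "A"))
  flipped <- tab
  flipped$measure <- stats::relevel(flipped$measure, ref = "survival")
  f2 <- suppressWarnings(fit_weighted_lmm(flipped, "A"))
  b1 <- f1$coefficients
  b2 <- f2$coefficients
  expect_equal(b2$estimate[2], -b1$estimate[2], tolerance = 1e-6)
  expect_equal(fitted(f1$fit), fitted(f2$fit), tolerance = 1e-6)
})

test_that("rescaling all weights by a constant changes nothing that matters", {
  tab <- simulate_coefficient_table(n_species = 12, n_schemes = 3, seed = 10)
  scaled <- tab
  scaled$se <- scaled$se * 3.7    # w -> w / 3.7^2
  f1 <- suppressWarnings(fit_weighted_lmm(tab, "A"))
  f2 <- suppressWarnings(fit_weighted_lmm(scaled, "A"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-5)
  expect_equal(f1$coefficients$t, f2$coefficients$t, tolerance = 1e-4)
})

test_that("models B and C expose the documented fixed-effect structure", {
  tab <- simulate_coefficient_table(n_species = 12, n_schemes = 4, seed = 2)
  fb <- suppressWarnings(fit_weighted_lmm(tab, "B"))
  expect_setequal(fb$coefficients$parameter,
                  c("(Intercept)", "measuresurvival", "mean_temp_c",
                    "measuresurvival:mean_temp_c"))
  fc <- suppressWarnings(fit_weighted_lmm(tab, "C"))
  expect_equal(nrow(fc$coefficients), 6)
  expect_true(all(c("measuresurvival:migrationshort/resident",
                    "measuresurvival:habitatreed") %in%
                    fc$coefficients$parameter))
  expect_true(all(is.finite(fc$coefficients$df)))
})

test_that("temperature predictions follow the fitted linear structure", {
  tab <- simulate_coefficient_table(n_species = 14, n_schemes = 5,
                                    beta_temp = -0.005,
                                    beta_survival_temp = 0, seed = 13)
  fit <- suppressWarnings(fit_weighted_lmm(tab, "B"))
  grid <- seq(min(tab$mean_temp_c), max(tab$mean_temp_c), length.out = 5)
  pred <- temperature_gradient_prediction(fit, grid)
  beta <- lme4::fixef(fit$fit)
  # hand-computed linear predictor for the survival measure at grid point 3
  expect_equal(pred$predicted[pred$measure == "survival"][3],
               unname(beta["(Intercept)"] + beta["measuresurvival"] +
                        (beta["mean_temp_c"] +
                           beta["measuresurvival:mean_temp_c"]) * grid[3]),
               tolerance = 1e-10)
  # zero interaction truth: fitted lines are near-parallel
  gap <- pred$predicted[pred$measure == "survival"] -
    pred$predicted[pred$measure == "productivity"]
  expect_lt(diff(range(gap)), 0.05)
  expect_warning(temperature_gradient_prediction(fit, max(grid) + 10),
                 "beyond")
})

test_that("the coefficient-table generator honours its noise-free limit", {
  tab <- simulate_coefficient_table(n_species = 10, n_schemes = 2,
                                    sd_species = 0, sd_scheme = 0,
                                    sd_resid = 0, seed = 5)
  expect_equal(unique(tab$coefficient[tab$measure == "productivity"]), 0.061)
  expect_equal(unique(tab$coefficient[tab$measure == "survival"]),
               0.061 + 0.019)
  t2 <- simulate_coefficient_table(n_species = 10, n_schemes = 2,
                                   sd_species = 0, sd_scheme = 0,
                                   sd_resid = 0, seed = 99)
  expect_equal(tab$coefficient, t2$coefficient)  # deterministic limit
  expect_error(simulate_coefficient_table(n_species = 2, n_schemes = 2),
               "at least 20")
  expect_error(simulate_coefficient_table(sd_species = -1), "non-negative")
})

test_that("the measure-effect difference obeys the law of large numbers", {
  tab <- simulate_coefficient_table(n_species = 150, n_schemes = 8,
                                    beta_survival = 0.02, sd_species = 0.01,
                                    sd_scheme = 0.01, sd_resid = 0.03,
                                    seed = 77)
  gap <- mean(tab$coefficient[tab$measure == "survival"]) -
    mean(tab$coefficient[tab$measure == "productivity"])
  expect_lt(abs(gap - 0.02), 0.004)
})
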