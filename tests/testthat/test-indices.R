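make_counts <- function(site, year, adults, juveniles) {
  structure(data.frame(site = site, year = year, adults = adults,
                       juveniles = juveniles, stringsAsFactors = FALSE),
            class = c("site_year_counts", "data.frame"),
            species = "SP01", scheme = "X")
}

test_that("tabulation counts distinct individuals per site-year", {
  rows <- rbind(cap("A1", year = 2005, visit = 1),
                cap("A1", year = 2005, visit = 5),  # same bird twice
                cap("A2", year = 2005, visit = 2),
                cap("A3", year = 2005, visit = 3),
                cap("J1", year = 2005, visit = 1, age = "J"),
                cap("J2", year = 2005, visit = 2, age = "J"),
                cap("J9", year = 2006, visit = 2, age = "J"))
  counts <- tabulate_counts(capture_table(rows), "SP01", "X")
  r05 <- counts[counts$year == 2005, ]
  expect_equal(r05$adults, 3)
  expect_equal(r05$juveniles, 2)
  # juvenile-only site-year keeps its zero-adult row
  r06 <- counts[counts$year == 2006, ]
  expect_equal(r06$adults, 0)
  expect_equal(r06$juveniles, 1)
})

test_that("single-site productivity reproduces the annual proportions", {
  counts <- make_counts("S1", 2005:2008, adults = c(10, 8, 12, 9),
                        juveniles = c(10, 12, 6, 9))
  series <- fit_productivity_glm(counts)
  expect_equal(series$estimates$estimate,
               c(10, 12, 6, 9) / c(20, 20, 18, 18), tolerance = 1e-7)
})

test_that("single-site abundance index is the count ratio to year one", {
  counts <- make_counts("S1", 2005:2006, adults = c(10, 12),
                        juveniles = c(0, 0))
  series <- fit_abundance_glm(counts)
  expect_equal(series$estimates$estimate, c(1, 1.2), tolerance = 1e-7)
  expect_equal(series$estimates$se[1], 0)
})

test_that("identical sites produce zero site effects and pooled estimates", {
  counts <- make_counts(rep(c("S1", "S2"), each = 3), rep(2005:2007, 2),
                        adults = rep(c(10, 8, 12), 2),
                        juveniles = rep(c(10, 12, 6), 2))
  series <- fit_productivity_glm(counts)
  expect_equal(series$estimates$estimate,
               c(10, 12, 6) / c(20, 20, 18), tolerance = 1e-6)
  site_coef <- coef(series$fit)[grep("^site", names(coef(series$fit)))]
  expect_equal(unname(site_coef), 0, tolerance = 1e-6)
})

test_that("doubling every site's counts leaves index ratios unchanged", {
  counts <- make_counts(rep(c("S1", "S2"), each = 4), rep(2005:2008, 2),
                        adults = c(10, 12, 9, 11, 20, 24, 18, 22),
                        juveniles = 0)
  s1 <- fit_abundance_glm(counts)
  doubled <- counts
  doubled$adults <- doubled$adults * 2
  s2 <- fit_abundance_glm(doubled)
  expect_equal(s1$estimates$estimate, s2$estimates$estimate,
               tolerance = 1e-8)
})

test_that("Pearson dispersion matches its definition and edge cases", {
  # exact two-site proportional data leave ~zero Pearson residuals with df>0
  counts <- make_counts(rep(c("S1", "S2"), each = 3), rep(2005:2007, 2),
                        adults = c(10, 20, 40, 10, 20, 40), juveniles = 0)
  fit <- glm(adults ~ factor(site) + factor(year), family = quasipoisson(),
             data = counts)
  expect_gt(df.residual(fit), 0)
  expect_lt(pearson_dispersion(fit), 1e-10)
  # saturated model: undefined
  sat <- glm(adults ~ factor(year), family = quasipoisson(),
             data = counts[1:3, ])
  expect_error(pearson_dispersion(sat), "df = 0")
})

test_that("dispersion is near 1 under Poisson/binomial truth and above 1
           when overdispersed", {
  set.seed(99)
  n_site <- 12
  n_year <- 8
  grid <- expand.grid(site = sprintf("S%02d", 1:n_site), year = 2000 + 1:n_year)
  disp_pois <- replicate(5, {
    counts <- make_counts(grid$site, grid$year,
                          adults = rpois(nrow(grid), 30), juveniles = 0)
    fit_abundance_glm(counts)$dispersion
  })
  expect_true(all(abs(disp_pois - 1) < 0.45))
  # beta-binomial style overdispersion for productivity
  disp_bb <- replicate(5, {
    n_tot <- 60
    pr <- rbeta(nrow(grid), 6, 4)          # mean 0.6, strong extra variance
    juv <- rbinom(nrow(grid), n_tot, pr)
    counts <- make_counts(grid$site, grid$year, adults = n_tot - juv,
                          juveniles = juv)
    fit_productivity_glm(counts)$dispersion
  })
  expect_true(all(disp_bb > 1.5))
})

test_that("index SEs scale with the square root of the dispersion", {
  set.seed(7)
  grid <- expand.grid(site = sprintf("S%02d", 1:8), year = 2000 + 1:6)
  counts <- make_counts(grid$site, grid$year,
                        adults = rnbinom(nrow(grid), mu = 30, size = 3),
                        juveniles = 0)
  series <- fit_abundance_glm(counts)
  disp <- series$dispersion
  V1 <- summary(series$fit, dispersion = 1)$cov.scaled
  yn <- paste0("year", series$estimates$year[-1])
  se_unscaled <- series$estimates$estimate[-1] * sqrt(diag(V1)[yn])
  expect_equal(series$estimates$se[-1], unname(se_unscaled) * sqrt(disp),
               tolerance = 1e-8)
})

test_that("the dispersion filter drops at four and keeps below it", {
  expect_false(filter_by_dispersion(c(1.3, 4.2))$keep)
  expect_true(filter_by_dispersion(c(1.3, 2.0))$keep)
  expect_false(filter_by_dispersion(4.0)$keep)   # "under four" is strict
  expect_true(filter_by_dispersion(3.999)$keep)
})

test_that("annual indices recover the generator's truth", {
  cfg <- simulation_config(n_schemes = 1, n_species = 1, n_sites = 20,
                           n_years = 8, mean_rho = 0.58, rho_sd = 0.04,
                           seed = 41)
  sim <- simulate_scheme(cfg, "SCH01")
  truth <- sim$truth$SP01
  counts <- tabulate_counts(sim$table, "SP01", "SCH01")
  prod <- fit_productivity_glm(counts)
  expect_true(all(abs(prod$estimates$estimate - truth$rho) < 0.05))
  abund <- fit_abundance_glm(counts)
  expected <- colSums(truth$expected_adult_captures)
  truth_ratio <- expected / expected[1]
  expect_true(all(abs(abund$estimates$estimate / truth_ratio - 1) < 0.12))
})
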