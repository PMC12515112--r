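# Directly simulated step-2 coefficient tables with known fixed-effect truth,
# for testing the step-3 meta-models in isolation.

#' Simulate a stacked coefficient table with known truth
#'
#' Generates one coefficient row per (species, scheme, measure) as
#' `fixed-effect prediction + species intercept + scheme intercept +
#' residual`, where the residual standard deviation of row `k` is
#' `sd_resid * u_k` with `u_k` drawn uniformly from `se_scale_range`; the
#' reported row SE is exactly that residual SD, so `weight = 1/SE^2` is the
#' correct inverse-variance weight.
#'
#' Fixed effects default to a structure in which productivity (the reference
#' measure) has a positive mean coefficient and survival adds a small
#' positive offset; temperature and trait interactions default to zero and
#' can be switched on for model-B/C recovery studies.
#'
#' @param n_species,n_schemes table dimensions (rows =
#'   `n_species * n_schemes * 2`, which must be at least 20).
#' @param intercept mean coefficient of the reference measure
#'   (productivity).
#' @param beta_survival additive fixed effect of the survival measure.
#' @param beta_temp,beta_survival_temp temperature main effect and its
#'   interaction with the survival measure (per degree C).
#' @param beta_migration,beta_survival_migration migration-group
#'   (short/resident vs long-distance) main effect and interaction.
#' @param beta_habitat,beta_survival_habitat habitat-group (reed vs forest)
#'   main effect and interaction.
#' @param sd_species,sd_scheme random-intercept SDs.
#' @param sd_resid baseline residual SD (scaled per row, see above).
#' @param se_scale_range range of the per-row SE multipliers.
#' @param temp_range range of scheme temperatures (degrees C).
#' @param seed integer RNG seed.
#' @return A `meta_table` (see [stack_coefficients()]) with a `truth`
#'   attribute listing every generating parameter.
#' @export
simulate_coefficient_table <- function(n_species = 30, n_schemes = 4,
                                       intercept = 0.061,
                                       beta_survival = 0.019,
                                       beta_temp = 0,
                                       beta_survival_temp = 0,
                                       beta_migration = 0,
                                       beta_survival_migration = 0,
                                       beta_habitat = 0,
                                       beta_survival_habitat = 0,
                                       sd_species = 0.02, sd_scheme = 0.02,
                                       sd_resid = 0.05,
                                       se_scale_range = c(0.5, 1.5),
                                       temp_range = c(8, 18), seed = 1) {
  if (any(c(sd_species, sd_scheme, sd_resid) < 0)) {
    stop("config error: standard deviations must be non-negative")
  }
  n_rows <- n_species * n_schemes * 2
  if (n_rows < 20) stop("config error: need at least 20 rows")
  set.seed(seed)
  species <- sprintf("SP%03d", seq_len(n_species))
  schemes <- sprintf("SCH%02d", seq_len(n_schemes))
  migration <- rep(MIGRATION_LEVELS, length.out = n_species)
  habitat <- rep(rep(HABITAT_LEVELS, each = 2), length.out = n_species)
  temps <- stats::runif(n_schemes, temp_range[1], temp_range[2])
  b_species <- stats::rnorm(n_species, 0, sd_species)
  b_scheme <- stats::rnorm(n_schemes, 0, sd_scheme)
  grid <- expand.grid(species_i = seq_len(n_species),
                      scheme_i = seq_len(n_schemes),
                      measure = MEASURE_LEVELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  is_surv <- as.numeric(grid$measure == "survival")
  is_short <- as.numeric(migration[grid$species_i] == MIGRATION_LEVELS[2])
  is_reed <- as.numeric(habitat[grid$species_i] == HABITAT_LEVELS[2])
  temp <- temps[grid$scheme_i]
  lp <- intercept + beta_survival * is_surv +
    beta_temp * temp + beta_survival_temp * is_surv * temp +
    beta_migration * is_short + beta_survival_migration * is_surv * is_short +
    beta_habitat * is_reed + beta_survival_habitat * is_surv * is_reed
  u <- stats::runif(n_rows, se_scale_range[1], se_scale_range[2])
  row_sd <- sd_resid * u
  value <- lp + b_species[grid$species_i] + b_scheme[grid$scheme_i] +
    stats::rnorm(n_rows, 0, row_sd)
  se <- row_sd
  if (all(se == 0)) se <- rep(1, n_rows)  # noise-free limit: unit weights
  out <- data.frame(
    scheme = schemes[grid$scheme_i], species = species[grid$species_i],
    measure = factor(grid$measure, levels = MEASURE_LEVELS),
    coefficient = value, se = se,
    mean_temp_c = temp,
    migration = factor(migration[grid$species_i],
                       levels = MIGRATION_LEVELS),
    habitat = factor(habitat[grid$species_i], levels = HABITAT_LEVELS),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("meta_table", "data.frame"),
            truth = list(intercept = intercept,
                         beta_survival = beta_survival,
                         beta_temp = beta_temp,
                         beta_survival_temp = beta_survival_temp,
                         beta_migration = beta_migration,
                         beta_survival_migration = beta_survival_migration,
                         beta_habitat = beta_habitat,
                         beta_survival_habitat = beta_survival_habitat,
                         sd_species = sd_species, sd_scheme = sd_scheme,
                         sd_resid = sd_resid, seed = seed))
}
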