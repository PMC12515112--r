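# Multi-scheme synthetic CES capture data with known demographic truth.
#
# Generative process per scheme, species and site:
#   - new adults captured in year t ~ Poisson(lambda_{s,t});
#   - each newly captured adult is a resident with probability tau, otherwise
#     a transient that never reappears;
#   - residents survive the interval t -> t+1 with probability phi_t (shared
#     across sites) and, while alive, are re-detected at their site with the
#     site recapture probability p_s each year;
#   - juvenile captures ~ Poisson(E[A_t] * rho_t / (1 - rho_t)), independent
#     of the realized adult captures A_t; since A_t is itself marginally
#     Poisson, the juvenile count given the total is exactly
#     Binomial(total, rho_t), so the juvenile proportion has expectation
#     rho_t and the event-trial productivity model sees binomial truth;
#   - visit labels are uniform on 1..12 (downstream analysis collapses to
#     annual detections; visit structure only has to exercise the filters).
#
# log lambda_{s,t} = log(base lambda) + site effect + cumulative year effect,
# with year-effect increments coupled to the survival and productivity
# anomalies so that population growth genuinely carries a demographic signal.

#' Configuration for the synthetic multi-scheme CES simulation
#'
#' Realizes all scheme-, species-, site- and year-level parameters from the
#' given seed and stores them, so the generated data come with full truth
#' bookkeeping. Defaults describe a realistic constant-effort study: annual
#' adult survival around 0.5, residency probability 0.7, site recapture
#' probabilities between 0.3 and 0.6, juvenile proportions around 0.58, and
#' on the order of a dozen newly captured adults per site and year.
#'
#' @param n_schemes number of ringing schemes (each a country-level unit).
#' @param n_species number of species (traits alternate between the two
#'   migration and habitat groups).
#' @param n_sites sites per scheme.
#' @param n_years study years per scheme (`T >= 5`).
#' @param base_year first calendar year.
#' @param mean_phi,phi_sd mean and between-year SD of true annual adult
#'   survival (draws are clamped to (0.05, 0.95)).
#' @param tau residency probability of newly captured adults.
#' @param p_range range of site recapture probabilities (uniform draw).
#' @param mean_rho,rho_sd mean and between-year SD of the true juvenile
#'   proportion (clamped to (0.05, 0.95)).
#' @param base_lambda_range range of species base expected new-adult counts
#'   per site-year.
#' @param site_sd SD of site effects on log expected counts.
#' @param growth_sd SD of the annual log-abundance increments beyond the
#'   demographic coupling.
#' @param coupling_phi,coupling_rho coupling of the log-abundance increment
#'   in year t -> t+1 to the survival anomaly of interval t and the
#'   productivity anomaly of year t.
#' @param temp_range range of scheme mean breeding-season temperatures (C).
#' @param seed integer RNG seed; the per-scheme data stream is seeded as
#'   `seed + scheme index`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_schemes = 3, n_species = 4, n_sites = 15,
                              n_years = 12, base_year = 2005,
                              mean_phi = 0.5, phi_sd = 0.05, tau = 0.7,
                              p_range = c(0.3, 0.6),
                              mean_rho = 0.58, rho_sd = 0.05,
                              base_lambda_range = c(8, 16),
                              site_sd = 0.3, growth_sd = 0.05,
                              coupling_phi = 1.0, coupling_rho = 0.4,
                              temp_range = c(8, 18), seed = 1) {
  if (n_years < 5) stop("config error: need T >= 5 study years")
  if (mean_phi < 0 || mean_phi > 1) {
    stop("config error: mean_phi must lie in [0, 1]")
  }
  probs <- c(tau, p_range, mean_rho)
  if (any(probs <= 0) || any(probs > 1) || mean_rho >= 1) {
    stop("config error: probabilities must lie in (0, 1]")
  }
  if (any(base_lambda_range <= 0)) {
    stop("config error: expected counts must be positive")
  }
  set.seed(seed)
  scheme_codes <- sprintf("SCH%02d", seq_len(n_schemes))
  species_codes <- sprintf("SP%02d", seq_len(n_species))
  clamp <- function(x) pmin(pmax(x, 0.05), 0.95)
  traits <- data.frame(
    species = species_codes,
    migration = rep(MIGRATION_LEVELS, length.out = n_species),
    habitat = rep(rep(HABITAT_LEVELS, each = 2), length.out = n_species),
    stringsAsFactors = FALSE)
  temps <- data.frame(
    scheme = scheme_codes,
    mean_temp_c = stats::runif(n_schemes, temp_range[1], temp_range[2]),
    stringsAsFactors = FALSE)
  schemes <- vector("list", n_schemes)
  names(schemes) <- scheme_codes
  years <- base_year + seq_len(n_years) - 1
  for (g in seq_len(n_schemes)) {
    p_sites <- stats::runif(n_sites, p_range[1], p_range[2])
    names(p_sites) <- sprintf("%s-S%02d", scheme_codes[g], seq_len(n_sites))
    sp <- vector("list", n_species)
    names(sp) <- species_codes
    for (j in seq_len(n_species)) {
      phi <- if (phi_sd == 0) rep(mean_phi, n_years - 1) else
        clamp(stats::rnorm(n_years - 1, mean_phi, phi_sd))
      rho <- if (rho_sd == 0) rep(mean_rho, n_years) else
        clamp(stats::rnorm(n_years, mean_rho, rho_sd))
      base_lambda <- stats::runif(1, base_lambda_range[1],
                                  base_lambda_range[2])
      site_eff <- stats::rnorm(n_sites, 0, site_sd)
      incr <- coupling_phi * (phi - mean_phi) +
        coupling_rho * (rho[seq_len(n_years - 1)] - mean_rho) +
        stats::rnorm(n_years - 1, 0, growth_sd)
      year_eff <- c(0, cumsum(incr))
      lambda <- exp(log(base_lambda) +
                      outer(site_eff, year_eff, "+"))  # sites x years
      dimnames(lambda) <- list(names(p_sites), years)
      sp[[j]] <- list(phi = phi, tau = tau, rho = rho, lambda = lambda)
    }
    schemes[[g]] <- list(code = scheme_codes[g], years = years,
                         p_sites = p_sites, species = sp)
  }
  structure(list(n_schemes = n_schemes, n_species = n_species,
                 n_sites = n_sites, n_years = n_years, years = years,
                 scheme_codes = scheme_codes, species_codes = species_codes,
                 traits = traits, temperatures = temps, schemes = schemes,
                 seed = seed),
            class = "simulation_config")
}

# exact expected adult captures per site-year under the generative process:
# E[A_{s,t}] = lambda_{s,t} + M_t p_s with M_1 = 0 and
# M_{t+1} = (M_t + lambda_{s,t} tau) phi_t  (expected marked residents alive)
expected_adult_captures <- function(lambda, tau, phi, p_sites) {
  T_n <- ncol(lambda)
  out <- lambda
  M <- numeric(nrow(lambda))
  for (t in seq_len(T_n)) {
    out[, t] <- lambda[, t] + M * p_sites
    if (t < T_n) M <- (M + lambda[, t] * tau) * phi[t]
  }
  out
}

#' Simulate capture data for one scheme
#'
#' Draws the capture records of every species at every site of one scheme
#' under the documented generative process, with its own RNG stream seeded as
#' `seed + scheme index` so schemes can be regenerated independently.
#'
#' @param config a [simulation_config()].
#' @param scheme scheme code from the config.
#' @return list with `table` (a [capture_table()]) and `truth` (per-species
#'   list of the true `phi`, `tau`, `rho`, site recapture probabilities,
#'   `lambda` and the exact expected adult captures per site-year).
#' @export
simulate_scheme <- function(config, scheme) {
  stopifnot(inherits(config, "simulation_config"))
  g <- match(scheme, config$scheme_codes)
  if (is.na(g)) stop("unknown scheme: ", scheme)
  sch <- config$schemes[[g]]
  set.seed(config$seed + g)
  years <- sch$years
  T_n <- length(years)
  acc_id <- list()
  acc_sp <- list()
  acc_site <- list()
  acc_year <- list()
  acc_age <- list()
  push <- function(ids, sp, site, year, age) {
    i <- length(acc_id) + 1
    acc_id[[i]] <<- ids
    acc_sp[[i]] <<- rep(sp, length(ids))
    acc_site[[i]] <<- rep(site, length(ids))
    acc_year[[i]] <<- rep(year, length(ids))
    acc_age[[i]] <<- rep(age, length(ids))
  }
  truth <- list()
  counter <- 0L
  for (sp_code in names(sch$species)) {
    spp <- sch$species[[sp_code]]
    exp_adults <- expected_adult_captures(spp$lambda, spp$tau, spp$phi,
                                          sch$p_sites)
    truth[[sp_code]] <- list(
      phi = spp$phi, tau = spp$tau, rho = spp$rho,
      p_sites = sch$p_sites, lambda = spp$lambda,
      expected_adult_captures = exp_adults)
    for (s in seq_along(sch$p_sites)) {
      site <- names(sch$p_sites)[s]
      p_s <- sch$p_sites[s]
      alive <- character(0)  # marked residents currently alive at the site
      for (t in seq_len(T_n)) {
        n_new <- stats::rpois(1, spp$lambda[s, t])
        new_ids <- if (n_new > 0) {
          sprintf("%s-%s-%06d", sch$code, sp_code, counter + seq_len(n_new))
        } else {
          character(0)
        }
        counter <- counter + n_new
        redetected <- alive[stats::runif(length(alive)) < p_s]
        adult_ids <- c(new_ids, redetected)
        n_adults <- length(adult_ids)
        if (n_adults > 0) push(adult_ids, sp_code, site, years[t], "A")
        n_juv <- stats::rpois(1, exp_adults[s, t] * spp$rho[t] /
                                (1 - spp$rho[t]))
        if (n_juv > 0) {
          juv_ids <- sprintf("%s-%s-J%06d", sch$code, sp_code,
                             counter + seq_len(n_juv))
          counter <- counter + n_juv
          push(juv_ids, sp_code, site, years[t], "J")
        }
        # recruitment into the resident pool and survival to t + 1
        residents_new <- new_ids[stats::runif(length(new_ids)) < spp$tau]
        pool <- c(alive, residents_new)
        if (t < T_n) {
          alive <- pool[stats::runif(length(pool)) < spp$phi[t]]
        }
      }
    }
  }
  n_rows <- sum(lengths(acc_id))
  df <- data.frame(ring_id = unlist(acc_id, use.names = FALSE),
                   species = unlist(acc_sp, use.names = FALSE),
                   scheme = sch$code,
                   site = unlist(acc_site, use.names = FALSE),
                   year = unlist(acc_year, use.names = FALSE),
                   visit = sample.int(12, n_rows, replace = TRUE),
                   age_class = unlist(acc_age, use.names = FALSE),
                   stringsAsFactors = FALSE)
  tbl <- capture_table(df, provenance = sprintf("simulated seed=%d scheme=%s",
                                                config$seed, sch$code))
  list(table = tbl, truth = truth)
}

#' Simulate all schemes plus covariate tables
#'
#' @param config a [simulation_config()] with at least two schemes and two
#'   species of differing traits.
#' @return list with `table` (combined [capture_table()]), `traits`,
#'   `temperatures` and `truth` (per-scheme list as in [simulate_scheme()]).
#' @export
simulate_multischeme <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (anyDuplicated(config$scheme_codes)) {
    stop("config error: duplicate scheme codes")
  }
  tables <- list()
  truth <- list()
  for (code in config$scheme_codes) {
    sim <- simulate_scheme(config, code)
    tables[[code]] <- as.data.frame(sim$table)
    truth[[code]] <- sim$truth
  }
  df <- do.call(rbind, tables)
  rownames(df) <- NULL
  tbl <- capture_table(df, provenance = sprintf("simulated seed=%d",
                                                config$seed))
  list(table = tbl, traits = config$traits,
       temperatures = config$temperatures, truth = truth)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the capture table (CSV), `traits.csv`, `temperature.csv` and
#' `truth.json` into a directory.
#'
#' @param sim a [simulate_multischeme()] result.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_capture_table(sim$table, file.path(dir, "captures.csv"))
  utils::write.csv(sim$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$temperatures, file.path(dir, "temperature.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
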