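test_that("history probabilities sum to one over all possible histories", {
  grid <- expand.grid(phi0 = c(0.2, 0.55, 0.9), tau = c(0.4, 0.7, 1),
                      p = c(0.15, 0.5, 0.85))
  for (T_n in c(4, 6)) {
    for (i in seq_len(nrow(grid))) {
      phi <- rep(grid$phi0[i], T_n - 1)
      phi[1] <- min(0.95, phi[1] + 0.1)  # time variation
      for (f in c(1, 2)) {
        total <- total_history_probability(T_n, f, phi, grid$tau[i],
                                           grid$p[i])
        expect_equal(total, 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("tau = 1 reduces to the plain CJS likelihood", {
  set.seed(42)
  for (rep in 1:8) {
    T_n <- sample(4:6, 1)
    n <- 12
    first <- sample(seq_len(T_n - 1), n, replace = TRUE)
    det <- matrix(0L, n, T_n)
    for (i in seq_len(n)) {
      det[i, first[i]] <- 1L
      later <- seq(first[i] + 1, T_n)
      det[i, later] <- rbinom(length(later), 1, 0.5)
    }
    site <- sample(c("X1", "X2"), n, replace = TRUE)
    chs <- make_chs(det, first, site)
    phi <- runif(T_n - 1, 0.2, 0.9)
    p <- c(X1 = 0.35, X2 = 0.6)
    ours <- cjs_negloglik(chs, list(phi = phi, tau = 1, p = p))
    oracle <- oracle_plain_cjs_nll(chs, phi, as.list(p))
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("zero survival makes a single-capture history certain", {
  chs <- make_chs(matrix(c(0, 1, 0, 0), nrow = 1), first = 2, site = "X1")
  nll <- cjs_negloglik(chs, list(phi = rep(0, 3), tau = 0.7, p = c(X1 = 0.4)))
  expect_equal(nll, 0, tolerance = 1e-12)
})

test_that("parameter validation rejects malformed inputs", {
  chs <- make_chs(matrix(c(1, 1, 0), nrow = 1), first = 1, site = "X1")
  expect_error(cjs_negloglik(chs, list(phi = c(0.5, NaN), tau = 0.7,
                                       p = c(X1 = 0.4))), "non-finite")
  expect_error(cjs_negloglik(chs, list(phi = 0.5, tau = 0.7,
                                       p = c(X1 = 0.4))), "length")
  expect_error(cjs_negloglik(chs, list(phi = c(0.5, 0.5), tau = 1.2,
                                       p = c(X1 = 0.4))), "out of range")
})

test_that("perfect detection of residents gives the closed-form survival MLE", {
  cfg <- simulation_config(n_schemes = 1, n_species = 1, n_sites = 8,
                           n_years = 6, mean_phi = 0.6, phi_sd = 0, tau = 1,
                           p_range = c(1, 1), base_lambda_range = c(20, 20),
                           seed = 5)
  sim <- simulate_scheme(cfg, "SCH01")
  h <- build_histories(sim$table, "SP01", "SCH01")
  fit <- fit_cjs_transient(h, n_starts = 1, seed = 1)
  # with tau = p = 1 a bird detected at t is re-detected iff it survives,
  # so phi_hat_t is the fraction of year-t birds seen at t + 1
  det <- h$det
  for (t in seq_len(ncol(det) - 2)) {
    at_risk <- det[, t] == 1
    if (sum(at_risk) < 30) next
    crude <- mean(det[at_risk, t + 1])
    expect_equal(fit$phi$estimate[t], crude, tolerance = 0.02)
  }
})

test_that("a history set with no recaptures fails to fit", {
  det <- diag(4)
  chs <- make_chs(det, first = 1:4, site = rep("X1", 4))
  expect_error(fit_cjs_transient(chs), "no recapture")
})

test_that("estimates are invariant to individual order and site labels", {
  cfg <- simulation_config(n_schemes = 1, n_species = 1, n_sites = 4,
                           n_years = 6, seed = 9)
  sim <- simulate_scheme(cfg, "SCH01")
  h <- build_histories(sim$table, "SP01", "SCH01")
  perm <- sample(seq_len(nrow(h$det)))
  h2 <- h
  h2$det <- h$det[perm, ]
  h2$first <- h$first[perm]
  h2$site <- h$site[perm]
  h2$multi_site <- h$multi_site[perm]
  relabel <- setNames(sprintf("Z%02d", seq_along(unique(h$site))),
                      sort(unique(h$site)))
  h3 <- h
  h3$site <- unname(relabel[h$site])
  names(h3$site) <- names(h$site)
  f1 <- fit_cjs_transient(h, n_starts = 1, seed = 2)
  f2 <- fit_cjs_transient(h2, n_starts = 1, seed = 2)
  f3 <- fit_cjs_transient(h3, n_starts = 1, seed = 2)
  expect_equal(f1$phi$estimate, f2$phi$estimate, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$phi$estimate, f3$phi$estimate, tolerance = 1e-6)
  # site estimates follow the relabelling (Z codes sort like the originals)
  expect_equal(f1$p$estimate, f3$p$estimate, tolerance = 1e-6)
})

test_that("recapture filter keeps the quoted limits, excludes beyond them", {
  fit <- fake_cjs_fit(phi_se = rep(0.1, 4),
                      p_est = c(0.05, 0.10, 0.50, 0.90, 0.95))
  out <- filter_by_recapture(fit)
  expect_setequal(out$retained, c("S02", "S03", "S04"))
  expect_setequal(out$excluded$site, c("S01", "S05"))
})

test_that("survival-SE filter drops years outside the open (0.01, 0.25)", {
  fit <- fake_cjs_fit(phi_se = c(0.30, 0.005, 0.12, 0.25, 0.01, 0.0101),
                      p_est = 0.5)
  out <- filter_by_survival_se(fit)
  expect_setequal(out$retained, fit$phi$year_start[c(3, 6)])
  expect_equal(nrow(out$excluded), 4)
})

test_that("SE-filter variants produce nested retained sets", {
  fit <- fake_cjs_fit(phi_se = c(0.005, 0.05, 0.15, 0.22, 0.28, 0.35),
                      p_est = 0.5)
  r20 <- filter_by_survival_se(fit, upper = 0.20)$retained
  r25 <- filter_by_survival_se(fit, upper = 0.25)$retained
  r30 <- filter_by_survival_se(fit, upper = 0.30)$retained
  expect_true(all(r20 %in% r25))
  expect_true(all(r25 %in% r30))
  expect_gt(length(r30), length(r20))
})
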