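# Shared fixtures and independent oracles.

# quick capture-record constructor
cap <- function(ring, species = "SP01", scheme = "X", site = "X1",
                year = 2005, visit = 1, age = "A") {
  data.frame(ring_id = ring, species = species, scheme = scheme, site = site,
             year = year, visit = visit, age_class = age,
             stringsAsFactors = FALSE)
}

# capture table where site-year visit counts are prescribed:
# `spec_df` has columns site, year, n_visits
visits_fixture <- function(spec_df, scheme = "X") {
  rows <- NULL
  k <- 0
  for (i in seq_len(nrow(spec_df))) {
    for (v in seq_len(spec_df$n_visits[i])) {
      k <- k + 1
      rows <- rbind(rows, cap(sprintf("R%04d", k), scheme = scheme,
                              site = spec_df$site[i],
                              year = spec_df$year[i], visit = v))
    }
  }
  capture_table(rows)
}

# site-year block of n_ad adults and n_juv juveniles for one species
adults_juvs_fixture <- function(n_ad, n_juv, species = "SPA", site = "S1",
                                year = 2005, offset = 0) {
  rows <- NULL
  for (i in seq_len(n_ad)) {
    rows <- rbind(rows, cap(sprintf("%s-A%d-%d", species, i, offset),
                            species = species, site = site, year = year,
                            visit = i))
  }
  for (i in seq_len(n_juv)) {
    rows <- rbind(rows, cap(sprintf("%s-J%d-%d", species, i, offset),
                            species = species, site = site, year = year,
                            visit = i, age = "J"))
  }
  rows
}

# hand-built capture history set (bypasses build_histories)
make_chs <- function(det, first, site, years = NULL, species = "SP01",
                     scheme = "X") {
  det <- matrix(as.integer(det), nrow = length(first))
  if (is.null(years)) years <- 2000 + seq_len(ncol(det))
  ids <- sprintf("I%03d", seq_len(nrow(det)))
  dimnames(det) <- list(ids, years)
  names(first) <- ids
  names(site) <- ids
  structure(list(species = species, scheme = scheme, years = years,
                 det = det, first = first, site = site,
                 multi_site = stats::setNames(rep(FALSE, length(first)), ids)),
            class = "capture_history_set")
}

# independent textbook CJS negative log-likelihood (no transience):
# straightforward per-individual products with a recursive chi
oracle_plain_cjs_nll <- function(chs, phi, p_by_site) {
  T_n <- ncol(chs$det)
  chi_rec <- function(t, p) {
    if (t == T_n) return(1)
    (1 - phi[t]) + phi[t] * (1 - p) * chi_rec(t + 1, p)
  }
  nll <- 0
  for (i in seq_len(nrow(chs$det))) {
    y <- chs$det[i, ]
    f <- chs$first[i]
    l <- max(which(y == 1))
    p <- p_by_site[[chs$site[i]]]
    L <- 1
    if (l > f) {
      for (t in f:(l - 1)) {
        L <- L * phi[t] * (if (y[t + 1] == 1) p else 1 - p)
      }
    }
    L <- L * chi_rec(l, p)
    nll <- nll - log(L)
  }
  nll
}

# total probability over all 2^(T-f) post-first-capture histories of one
# individual, evaluated through the package likelihood
total_history_probability <- function(T_n, f, phi, tau, p) {
  n_free <- T_n - f
  total <- 0
  for (code in 0:(2^n_free - 1)) {
    det <- integer(T_n)
    det[f] <- 1L
    if (n_free > 0) {
      bits <- as.integer(intToBits(code))[seq_len(n_free)]
      det[(f + 1):T_n] <- bits
    }
    chs <- make_chs(matrix(det, nrow = 1), first = f, site = "X1")
    nll <- cjs_negloglik(chs, list(phi = phi, tau = tau, p = c(X1 = p)))
    total <- total + exp(-nll)
  }
  total
}

# weighted least squares through the normal equations
oracle_wls <- function(X, y, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)
}

# chi recursion evaluated at truth (independent of the package internals)
oracle_chi <- function(phi, p, T_n) {
  chi <- numeric(T_n)
  chi[T_n] <- 1
  for (t in (T_n - 1):1) chi[t] <- (1 - phi[t]) + phi[t] * (1 - p) * chi[t + 1]
  chi
}

# synthetic cjs_fit skeleton for filter tests
fake_cjs_fit <- function(phi_se, p_est, years = NULL) {
  n <- length(phi_se)
  if (is.null(years)) years <- 2000 + seq_len(n)
  structure(list(species = "SP01", scheme = "X",
                 years = c(years, max(years) + 1),
                 phi = data.frame(year_start = years,
                                  year_end = years + 1,
                                  estimate = rep(0.5, n), se = phi_se),
                 tau = 0.7, tau_se = 0.05,
                 p = data.frame(site = sprintf("S%02d", seq_along(p_est)),
                                estimate = p_est, se = rep(0.05,
                                                           length(p_est)),
                                stringsAsFactors = FALSE),
                 loglik = -1, converged = TRUE, ses_available = TRUE,
                 vcov_logit = NULL, n_dropped_final_year = 0,
                 n_individuals = 100),
            class = "cjs_fit")
}
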