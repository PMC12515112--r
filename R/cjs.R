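# Cormack-Jolly-Seber survival model with a transience mixture.
#
# Likelihood, conditional on first capture, for individual i first caught at
# occasion f at site s with last detection l:
#   L_i = (1 - tau) * 1[l == f]  +  tau * CJS_i
#   CJS_i = prod_{t=f..l-1} phi_t * [p_s if detected at t+1 else 1-p_s]
#           * chi_{s,l}
#   chi_{s,T} = 1;  chi_{s,t} = (1 - phi_t) + phi_t (1 - p_s) chi_{s,t+1}
# phi is annual and shared across sites within the scheme; p is constant over
# years within a site; tau is the probability a newly caught adult is a
# resident (transients never reappear).

log_clamp <- function(x) log(pmax(x, 1e-300))

# sufficient statistics: the likelihood depends on the histories only through
# per-site interval exposures, post-first detections/misses, last-detection
# counts and never-seen-again counts by first occasion.
cjs_stats <- function(chs) {
  stopifnot(inherits(chs, "capture_history_set"))
  det <- chs$det
  if (nrow(det) == 0) stop("empty history set")
  T_n <- ncol(det)
  f <- as.integer(chs$first)
  l <- apply(det, 1, function(v) max(which(v == 1L)))
  sites <- sort(unique(chs$site))
  s_idx <- match(chs$site, sites)
  S <- length(sites)

  drop_final <- f == T_n & l == T_n
  n_dropped_final <- sum(drop_final)

  seen <- l > f
  A <- matrix(0, S, T_n - 1)           # resident-interval exposures
  Lst <- matrix(0, S, T_n)             # last-detection counts (seen-again)
  N0 <- matrix(0, S, T_n)              # never-seen-again counts by first occ.
  D_tot <- numeric(S)                  # post-first detections
  M_tot <- numeric(S)                  # post-first misses
  n_seen <- numeric(S)
  for (s in seq_len(S)) {
    in_s <- s_idx == s & !drop_final
    sf <- f[in_s & seen]
    sl <- l[in_s & seen]
    if (length(sf) > 0) {
      for (t in seq_len(T_n - 1)) A[s, t] <- sum(sf <= t & sl > t)
      Lst[s, ] <- tabulate(sl, nbins = T_n)
      d <- det[in_s & seen, , drop = FALSE]
      n_det_after_first <- sum(d) - length(sf)
      D_tot[s] <- n_det_after_first
      M_tot[s] <- sum(sl - sf) - n_det_after_first
      n_seen[s] <- length(sf)
    }
    f0 <- f[in_s & !seen]
    if (length(f0) > 0) N0[s, ] <- tabulate(f0, nbins = T_n)
  }
  list(sites = sites, T_n = T_n, A = A, Lst = Lst, N0 = N0, D_tot = D_tot,
       M_tot = M_tot, n_seen = n_seen, n_dropped_final = n_dropped_final,
       any_recapture = any(seen & !drop_final))
}

chi_matrix <- function(phi, p, T_n) {
  S <- length(p)
  chi <- matrix(1, S, T_n)
  for (t in (T_n - 1):1) {
    chi[, t] <- (1 - phi[t]) + phi[t] * (1 - p) * chi[, t + 1]
  }
  chi
}

cjs_nll_stats <- function(stats, phi, tau, p) {
  T_n <- stats$T_n
  chi <- chi_matrix(phi, p, T_n)
  ll <- sum(stats$n_seen) * log_clamp(tau) +
    sum(stats$A %*% log_clamp(phi)) +
    sum(stats$D_tot * log_clamp(p)) +
    sum(stats$M_tot * log_clamp(1 - p)) +
    sum(stats$Lst * log_clamp(chi)) +
    sum(stats$N0 * log_clamp((1 - tau) + tau * chi))
  -ll
}

#' Negative log-likelihood of the transient-CJS model
#'
#' @param histories a [build_histories()] result.
#' @param params list with `phi` (length `T - 1` annual survival
#'   probabilities), `tau` (residency probability) and `p` (site recapture
#'   probabilities; a named vector keyed by site code, or unnamed in sorted
#'   site-code order).
#' @return The negative log-likelihood, conditional on first captures.
#' @export
cjs_negloglik <- function(histories, params) {
  stats <- cjs_stats(histories)
  phi <- params$phi
  tau <- params$tau
  p <- params$p
  if (length(phi) != stats$T_n - 1) {
    stop("phi must have length T - 1 = ", stats$T_n - 1)
  }
  if (!is.null(names(p))) {
    if (!all(stats$sites %in% names(p))) stop("p must cover all sites")
    p <- p[stats$sites]
  } else if (length(p) == 1) {
    p <- rep(p, length(stats$sites))
  } else if (length(p) != length(stats$sites)) {
    stop("p must have one entry per site (", length(stats$sites), ")")
  }
  vals <- c(phi, tau, p)
  if (any(!is.finite(vals))) stop("non-finite parameter value")
  if (any(phi < 0) || any(phi > 1) || any(p <= 0) || any(p >= 1) ||
      tau <= 0 || tau > 1) {
    stop("probabilities out of range: phi in [0, 1], p in (0, 1), ",
         "tau in (0, 1]")
  }
  cjs_nll_stats(stats, phi, tau, p)
}

#' Fit the transient-CJS model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimization on the logit scale with random restarts;
#' standard errors from the inverse observed information, transformed to the
#' probability scale by the delta method. Individuals first captured in the
#' final year carry no information and are dropped (counted in
#' `n_dropped_final_year`).
#'
#' @param histories a [build_histories()] result with `T >= 3` occasions.
#' @param n_starts number of random restarts (the first start is an informed
#'   start at crude data-based values).
#' @param seed integer seed controlling the restart jitter.
#' @return An object of class `cjs_fit` with elements `phi` (data frame:
#'   `year_start`, `year_end`, `estimate`, `se`), `tau`, `tau_se`, `p` (data
#'   frame: `site`, `estimate`, `se`), `loglik`, `converged`,
#'   `ses_available`, `vcov_logit`, `n_dropped_final_year`.
#' @export
fit_cjs_transient <- function(histories, n_starts = 5, seed = NULL) {
  stats <- cjs_stats(histories)
  T_n <- stats$T_n
  if (T_n < 3) stop("need at least 3 occasions to fit survival")
  if (!stats$any_recapture) {
    stop("convergence error: no recapture events in the history set")
  }
  S <- length(stats$sites)
  n_phi <- T_n - 1
  npar <- n_phi + 1 + S

  obj <- function(theta) {
    phi <- stats::plogis(theta[seq_len(n_phi)])
    tau <- stats::plogis(theta[n_phi + 1])
    p <- stats::plogis(theta[n_phi + 1 + seq_len(S)])
    cjs_nll_stats(stats, phi, tau, p)
  }

  # informed start: per-site crude recapture rate, mid-range survival
  p0 <- pmin(pmax(stats$D_tot / pmax(stats$D_tot + stats$M_tot, 1), 0.1), 0.8)
  theta0 <- c(rep(stats::qlogis(0.5), n_phi), stats::qlogis(0.7),
              stats::qlogis(p0))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  best <- NULL
  for (k in seq_len(max(1, n_starts))) {
    start <- if (k == 1) theta0 else theta0 + stats::rnorm(npar, 0, 0.75)
    fit <- tryCatch(
      stats::optim(start, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("convergence error: all optimization starts failed")

  theta <- best$par
  hess <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  vcov_logit <- NULL
  se_theta <- rep(NA_real_, npar)
  ses_available <- FALSE
  if (!is.null(hess)) {
    vcov_logit <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov_logit) && all(is.finite(diag(vcov_logit))) &&
        all(diag(vcov_logit) >= 0)) {
      se_theta <- sqrt(diag(vcov_logit))
      ses_available <- TRUE
    } else {
      vcov_logit <- NULL
    }
  }
  est <- stats::plogis(theta)
  se_prob <- se_theta * est * (1 - est)

  years <- histories$years
  phi_df <- data.frame(year_start = years[seq_len(n_phi)],
                       year_end = years[seq_len(n_phi) + 1],
                       estimate = est[seq_len(n_phi)],
                       se = se_prob[seq_len(n_phi)])
  p_df <- data.frame(site = stats$sites,
                     estimate = est[n_phi + 1 + seq_len(S)],
                     se = se_prob[n_phi + 1 + seq_len(S)],
                     stringsAsFactors = FALSE)
  structure(list(species = histories$species, scheme = histories$scheme,
                 years = years, phi = phi_df,
                 tau = est[n_phi + 1], tau_se = se_prob[n_phi + 1],
                 p = p_df, loglik = -best$value,
                 converged = best$convergence == 0,
                 ses_available = ses_available, vcov_logit = vcov_logit,
                 n_dropped_final_year = stats$n_dropped_final,
                 n_individuals = nrow(histories$det)),
            class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("<cjs_fit> ", x$species, " / ", x$scheme, ": ", x$n_individuals,
      " adults, logLik = ", format(x$loglik, digits = 6),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("tau =", format(x$tau, digits = 3), "+-",
      format(x$tau_se, digits = 3), "\n")
  print(x$phi, digits = 3)
  invisible(x)
}

#' Filter sites by estimated recapture probability
#'
#' Sites with unrealistically low or high recapture estimates
#' (`p < lower` or `p > upper`) are excluded from the species-specific
#' analysis; the quoted limits themselves are retained.
#'
#' @param fit a [fit_cjs_transient()] result.
#' @param lower,upper exclusion bounds (defaults 0.10 and 0.90).
#' @return list with `retained` (site codes) and `excluded` (data frame with
#'   site, estimate and triggering rule).
#' @export
filter_by_recapture <- function(fit, lower = 0.10, upper = 0.90) {
  stopifnot(inherits(fit, "cjs_fit"))
  if (!fit$converged) stop("recapture filter requires a converged fit")
  p <- fit$p
  bad <- p$estimate < lower | p$estimate > upper
  excluded <- data.frame(site = p$site[bad], estimate = p$estimate[bad],
                         rule = rep(sprintf("p outside [%g, %g]", lower,
                                            upper), sum(bad)),
                         stringsAsFactors = FALSE)
  list(retained = p$site[!bad], excluded = excluded)
}

#' Filter survival intervals by the size of their standard error
#'
#' Annual survival estimates are retained only when their SE (probability
#' scale) is smaller than `upper` but over `lower`; both bounds are
#' exclusive. Filtering is per species-scheme, so dropping a year for one
#' species does not affect another.
#'
#' @param fit a [fit_cjs_transient()] result.
#' @param lower,upper retention bounds (defaults 0.01 and 0.25, exclusive).
#' @return list with `retained` (interval start years) and `excluded`
#'   (data frame with year_start, se, rule).
#' @export
filter_by_survival_se <- function(fit, lower = 0.01, upper = 0.25) {
  stopifnot(inherits(fit, "cjs_fit"))
  phi <- fit$phi
  if (!fit$ses_available || any(!is.finite(phi$se))) {
    keep <- rep(FALSE, nrow(phi))
    rule <- "se unavailable"
  } else {
    keep <- phi$se > lower & phi$se < upper
    rule <- sprintf("se outside (%g, %g)", lower, upper)
  }
  list(retained = phi$year_start[keep],
       excluded = data.frame(year_start = phi$year_start[!keep],
                             se = phi$se[!keep],
                             rule = rep(rule, sum(!keep)),
                             stringsAsFactors = FALSE))
}
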