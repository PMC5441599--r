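# Parameter bounds keeping the optimizer in the physical region.
.time_bounds <- c(1e-12, 10)     # all relaxation/diffusion times, s
.amp_bounds <- c(0, 10)          # amplitudes
.T_bounds <- c(0, 0.99)          # triplet fraction
.N_bounds <- c(1e-4, 1e6)
.p_bounds <- c(0.5, 100)

# Sort a curve by lag and extract fitting ingredients; sigma = NULL gives
# unit weights with a warning, zero sigmas are floored to the smallest
# positive one.
curve_fit_data <- function(curve, expect_convention) {
  o <- order(curve$lag_s)
  lag <- curve$lag_s[o]
  y <- curve$value[o]
  if (curve$convention != expect_convention) {
    y <- y + if (expect_convention == "excess") -1 else 1
  }
  if (is.null(curve$sigma)) {
    warning("curve has no per-lag uncertainties; using unit weights")
    sigma <- rep(1, length(lag))
  } else {
    sigma <- curve$sigma[o]
    pos <- sigma[sigma > 0]
    if (length(pos) == 0L) sigma <- rep(1, length(lag))
    else sigma <- pmax(sigma, min(pos))
  }
  list(lag = lag, y = y, sigma = sigma)
}

run_lm <- function(par, fn, lower, upper, maxiter = 200) {
  minpack.lm::nls.lm(par = par, lower = lower, upper = upper, fn = fn,
                     control = minpack.lm::nls.lm.control(
                       maxiter = maxiter, ftol = 1e-12, ptol = 1e-12))
}

# 95% CIs from the (unscaled) covariance matrix solve(J'J) of the
# sigma-weighted residuals: doubling all sigmas doubles the CI widths and
# leaves the point estimates unchanged.
lm_uncertainty <- function(fit, par_names) {
  se <- rep(NA_real_, length(par_names))
  names(se) <- par_names
  covar <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(covar)) {
    d <- diag(covar)
    d[d < 0] <- NA_real_
    se[] <- sqrt(d)
  }
  se
}

at_bound_flags <- function(est, lower, upper) {
  tol <- 1e-6 * pmax(abs(est), 1e-300)
  (est - lower) <= pmax(tol, 1e-12 * (upper - lower)) |
    (upper - est) <= pmax(tol, 1e-12 * (upper - lower))
}

#' Fit the composite FCS model to a correlation curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt): minimizes
#' `sum(((G_data - G_model)/sigma)^2)` over the free parameters of the
#' model in [fcs_params()]. 95% confidence intervals come from the
#' covariance matrix at the optimum. Fits are deterministic given
#' identical inputs and starting point, and invariant to the ordering of
#' the input lags (the curve is sorted internally). Non-convergence and
#' parameters at their bounds are flagged on the result, not raised as
#' errors.
#'
#' Initial guesses, when not supplied, come from curve features (the
#' small-lag amplitude sets `gamma/N (1 + T/(1-T))(1 + sum a_r)`, the
#' half-decay lag sets `tau_D`) refined by a small deterministic
#' multistart over the decade of `tau_D`.
#'
#' @param curve a [correlation_curve()] with per-lag `sigma` (unit weights
#'   with a warning otherwise). Raw-convention curves are reduced by their
#'   baseline of 1; the model itself decays to 0.
#' @param n_dyn number of dynamic terms (0, 1 or 2).
#' @param triplet,antibunching include the triplet / antibunching factor.
#' @param gamma fixed shape correction (default `2^-3/2`).
#' @param p_free if `FALSE`, the axial ratio is held at its start value.
#' @param start optional named list/vector of starting values (full or
#'   partial; names as in the parameter vector below).
#' @param fixed optional named vector of parameters to hold fixed.
#' @param lower,upper optional named vectors overriding the default
#'   parameter bounds (e.g. restricting the triplet time to the
#'   microsecond range to keep the triplet and quenching bunching terms
#'   -- which share the same functional form -- from exchanging roles).
#' @param maxiter maximum LM iterations.
#'
#' @details Parameter names: `N`, `tau_D_s`, `p`, `A_ab`, `tau_ab_s`,
#'   `T_frac`, `tau_T_s`, `a_r1`, `tau_r1_s`, `a_r2`, `tau_r2_s`.
#'
#' @return object of class `fcs_fit`: estimates, `se`, `ci` (95%), weighted
#'   residuals, `chisq`/`redchisq`, convergence info, bound flags, and
#'   `params` (an [fcs_params()] at the optimum, for [isolate_dynamic()]).
#' @export
fit_fcs <- function(curve, n_dyn = 1L, triplet = TRUE, antibunching = FALSE,
                    gamma = 2^(-3 / 2), p_free = TRUE, start = NULL,
                    fixed = NULL, lower = NULL, upper = NULL,
                    maxiter = 200L) {
  stopifnot(inherits(curve, "correlation_curve"), n_dyn %in% 0:2)
  lower_over <- lower
  upper_over <- upper
  fd <- curve_fit_data(curve, "excess")
  par_names <- c("N", "tau_D_s", if (TRUE) "p",
                 if (antibunching) c("A_ab", "tau_ab_s"),
                 if (triplet) c("T_frac", "tau_T_s"),
                 if (n_dyn >= 1L) c("a_r1", "tau_r1_s"),
                 if (n_dyn == 2L) c("a_r2", "tau_r2_s"))
  lower <- c(N = .N_bounds[1], tau_D_s = .time_bounds[1], p = .p_bounds[1],
             A_ab = .amp_bounds[1], tau_ab_s = .time_bounds[1],
             T_frac = .T_bounds[1], tau_T_s = .time_bounds[1],
             a_r1 = .amp_bounds[1], tau_r1_s = .time_bounds[1],
             a_r2 = .amp_bounds[1], tau_r2_s = .time_bounds[1])[par_names]
  upper <- c(N = .N_bounds[2], tau_D_s = .time_bounds[2], p = .p_bounds[2],
             A_ab = .amp_bounds[2], tau_ab_s = .time_bounds[2],
             T_frac = .T_bounds[2], tau_T_s = .time_bounds[2],
             a_r1 = .amp_bounds[2], tau_r1_s = .time_bounds[2],
             a_r2 = .amp_bounds[2], tau_r2_s = .time_bounds[2])[par_names]
  if (!is.null(lower_over)) {
    nm <- intersect(names(lower_over), par_names)
    lower[nm] <- lower_over[nm]
  }
  if (!is.null(upper_over)) {
    nm <- intersect(names(upper_over), par_names)
    upper[nm] <- upper_over[nm]
  }

  model_at <- function(full) {
    dyn <- list()
    if (n_dyn >= 1L) dyn <- c(dyn, list(c(a_r = unname(full["a_r1"]),
                                          tau_r_s = unname(full["tau_r1_s"]))))
    if (n_dyn == 2L) dyn <- c(dyn, list(c(a_r = unname(full["a_r2"]),
                                          tau_r_s = unname(full["tau_r2_s"]))))
    pars <- fcs_params(N = full["N"], tau_D_s = full["tau_D_s"],
                       p = full["p"], gamma = gamma,
                       A_ab = if (antibunching) full["A_ab"] else 0,
                       tau_ab_s = if (antibunching) full["tau_ab_s"] else 2e-9,
                       T_frac = if (triplet) full["T_frac"] else 0,
                       tau_T_s = if (triplet) full["tau_T_s"] else 2.4e-6,
                       dyn = dyn)
    fcs_model(fd$lag, pars)
  }

  # --- starting values -------------------------------------------------
  A_tot <- max(fd$y)
  if (A_tot <= 0) A_tot <- 0.1
  idx_half <- which(fd$y < A_tot / 2)
  tau_half <- if (length(idx_half)) fd$lag[idx_half[1L]] else
    stats::median(fd$lag)
  base_start <- function(tau_D0) {
    s <- c(N = NA, tau_D_s = tau_D0, p = 5,
           A_ab = 0.7, tau_ab_s = 2e-9,
           T_frac = 0.15, tau_T_s = max(tau_D0 / 20, 5e-12),
           a_r1 = if (n_dyn >= 1L) 0.5 else 0,
           tau_r1_s = max(tau_D0 / 500, 2e-12),
           a_r2 = 0.3, tau_r2_s = max(tau_D0 / 5000, 1e-12))
    amp0 <- (if (triplet) 1 + s["T_frac"] / (1 - s["T_frac"]) else 1) *
      (1 + (if (n_dyn >= 1L) s["a_r1"] else 0) +
         (if (n_dyn == 2L) s["a_r2"] else 0))
    s["N"] <- unname(gamma * amp0 / A_tot)
    s[par_names]
  }
  starts <- lapply(c(1, 5, 1 / 5), function(f) base_start(tau_half * f))
  if (!is.null(start)) {
    s0 <- starts[[1L]]
    s0[names(start)] <- unlist(start)[names(start)]
    starts <- c(list(s0), starts)
  }

  fixed_full <- fixed
  if (!p_free && !("p" %in% names(fixed_full))) {
    fixed_full <- c(fixed_full, p = unname(starts[[1L]]["p"]))
  }
  free_names <- setdiff(par_names, names(fixed_full))
  resid_fn <- function(par_free) {
    full <- setNames(numeric(length(par_names)), par_names)
    full[free_names] <- par_free
    if (length(fixed_full)) full[names(fixed_full)] <- fixed_full
    (fd$y - model_at(full)) / fd$sigma
  }

  best <- NULL
  for (s in starts) {
    s_free <- pmin(pmax(s[free_names], lower[free_names]),
                   upper[free_names])
    fit <- tryCatch(run_lm(s_free, resid_fn, lower[free_names],
                           upper[free_names], maxiter),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("all starting points failed (degenerate curve?)")
  }
  est_free <- setNames(coef(best), free_names)
  est <- setNames(numeric(length(par_names)), par_names)
  est[free_names] <- est_free
  if (length(fixed_full)) est[names(fixed_full)] <- fixed_full
  se_free <- lm_uncertainty(best, free_names)
  se <- setNames(rep(NA_real_, length(par_names)), par_names)
  se[free_names] <- se_free
  z <- qnorm(0.975)
  ci <- cbind(lower = est - z * se, upper = est + z * se)
  chisq <- best$deviance
  n_free <- length(free_names)
  dyn <- list()
  if (n_dyn >= 1L) dyn <- c(dyn, list(c(a_r = unname(est["a_r1"]),
                                        tau_r_s = unname(est["tau_r1_s"]))))
  if (n_dyn == 2L) dyn <- c(dyn, list(c(a_r = unname(est["a_r2"]),
                                        tau_r_s = unname(est["tau_r2_s"]))))
  params <- fcs_params(N = est["N"], tau_D_s = est["tau_D_s"], p = est["p"],
                       gamma = gamma,
                       A_ab = if (antibunching) est["A_ab"] else 0,
                       tau_ab_s = if (antibunching) est["tau_ab_s"] else 2e-9,
                       T_frac = if (triplet) est["T_frac"] else 0,
                       tau_T_s = if (triplet) est["tau_T_s"] else 2.4e-6,
                       dyn = dyn)
  structure(list(estimate = est, se = se, ci = ci,
                 residuals = best$fvec, chisq = chisq,
                 redchisq = chisq / max(1L, length(fd$lag) - n_free),
                 n_lags = length(fd$lag), n_free = n_free,
                 converged = best$info %in% 1:4, info = best$info,
                 message = best$message,
                 at_bound = at_bound_flags(est_free, lower[free_names],
                                           upper[free_names]),
                 model = list(n_dyn = n_dyn, triplet = triplet,
                              antibunching = antibunching, gamma = gamma,
                              p_free = p_free, fixed = fixed_full),
                 params = params),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> %d dyn term(s), %s, red. chi^2 = %.3g\n",
              x$model$n_dyn,
              if (x$converged) "converged" else "NOT converged",
              x$redchisq))
  est <- x$estimate
  for (nm in names(est)) {
    cat(sprintf("  %-9s %.5g  (se %.3g)\n", nm, est[nm], x$se[nm]))
  }
  invisible(x)
}

# Weighted fit of a sum of `n_comp` decaying exponentials to an
# excess-convention curve; shared engine of fit_two_state and the model
# comparison.
fit_exp_components <- function(curve, n_comp = 1L, start = NULL,
                               maxiter = 200L) {
  fd <- curve_fit_data(curve, "excess")
  n <- length(fd$lag)
  par_names <- if (n_comp == 1L) c("a_r1", "tau_r1_s") else
    c("a_r1", "tau_r1_s", "a_r2", "tau_r2_s")
  lower <- setNames(rep(c(.amp_bounds[1], .time_bounds[1]), n_comp),
                    par_names)
  upper <- setNames(rep(c(.amp_bounds[2], .time_bounds[2]), n_comp),
                    par_names)
  model_at <- function(p) {
    g <- p["a_r1"] * exp(-fd$lag / p["tau_r1_s"])
    if (n_comp == 2L) g <- g + p["a_r2"] * exp(-fd$lag / p["tau_r2_s"])
    g
  }
  resid_fn <- function(p) (fd$y - model_at(setNames(p, par_names))) /
    fd$sigma
  # log-linear start from the positive part of the decay
  pos <- fd$y > max(fd$y) * 0.02 & fd$y > 0
  tau0 <- if (sum(pos) >= 3L) {
    sl <- coef(stats::lm(log(fd$y[pos]) ~ fd$lag[pos]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else fd$lag[ceiling(n / 3)]
  } else fd$lag[ceiling(n / 3)]
  a0 <- max(fd$y[1L], 1e-3)
  decaying <- mean(fd$y[seq_len(ceiling(n / 4))]) >
    mean(fd$y[seq.int(floor(3 * n / 4), n)])
  s0 <- if (n_comp == 1L) c(a_r1 = a0, tau_r1_s = tau0) else
    c(a_r1 = 0.6 * a0, tau_r1_s = tau0 / 3, a_r2 = 0.4 * a0,
      tau_r2_s = tau0 * 3)
  if (!is.null(start)) s0[names(start)] <- unlist(start)[names(start)]
  s0 <- pmin(pmax(s0, lower), upper)
  fit <- run_lm(s0, resid_fn, lower, upper, maxiter)
  est <- setNames(coef(fit), par_names)
  # enforce tau_r1 <= tau_r2 labeling for two components
  if (n_comp == 2L && est["tau_r1_s"] > est["tau_r2_s"]) {
    est <- est[c("a_r2", "tau_r2_s", "a_r1", "tau_r1_s")]
    names(est) <- par_names
  }
  se <- lm_uncertainty(fit, par_names)
  z <- qnorm(0.975)
  list(estimate = est, se = se,
       ci = cbind(lower = est - z * se, upper = est + z * se),
       residuals = fit$fvec, chisq = fit$deviance,
       redchisq = fit$deviance / max(1L, n - length(par_names)),
       n_lags = n, n_free = length(par_names),
       converged = (fit$info %in% 1:4) && decaying,
       non_decaying = !decaying, info = fit$info,
       at_bound = at_bound_flags(est, lower, upper))
}

#' Fit the two-state single-exponential model to a dynamic curve
#'
#' Weighted least-squares fit of `G_dyn(tau) = a_r exp(-tau/tau_r)` to an
#' excess-convention dynamic correlation curve, with microscopic contact
#' formation/dissociation rates attached via [rates_from_dynamics()].
#' A non-decaying input is flagged (`converged = FALSE`,
#' `non_decaying = TRUE`) rather than raised.
#'
#' @param curve an excess-convention [correlation_curve()] decaying toward
#'   zero.
#' @param start optional named starting values (`a_r1`, `tau_r1_s`).
#' @param convention rate convention for [rates_from_dynamics()].
#' @return object of class `dynamic_fit` with `a_r`, `tau_r_s`, `se`,
#'   `ci`, fit diagnostics, and `rates`.
#' @export
fit_two_state <- function(curve, start = NULL,
                          convention = c("as_printed", "telegraph_oracle")) {
  convention <- match.arg(convention)
  f <- fit_exp_components(curve, 1L, start = start)
  a_r <- unname(f$estimate["a_r1"])
  tau_r_s <- unname(f$estimate["tau_r1_s"])
  rates <- if (a_r > 0) rates_from_dynamics(a_r, tau_r_s, convention)
           else NULL
  structure(c(list(a_r = a_r, tau_r_s = tau_r_s, rates = rates,
                   convention = convention), f),
            class = "dynamic_fit")
}

#' @export
print.dynamic_fit <- function(x, ...) {
  cat(sprintf("<dynamic_fit> a_r = %.4g, tau_r = %.4g ns (%s)\n",
              x$a_r, x$tau_r_s / .ns,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$rates)) {
    cat(sprintf("  rates (%s): k_on = %.3g, k_off = %.3g us^-1\n",
                x$convention, x$rates$k_on_per_us, x$rates$k_off_per_us))
  }
  invisible(x)
}

#' Compare one- versus two-component dynamic models
#'
#' Fits the curve with one and with two dynamic components and reports the
#' reduced chi-squares, a lag-1 autocorrelation diagnostic of the weighted
#' residuals, and an F-test on the nested chi-squares
#' (`F = ((chi1 - chi2)/(df1 - df2)) / (chi2/df2)`). The recommendation is
#' advisory: the two-component model is preferred when the F-test p-value
#' falls below `alpha`.
#'
#' @param curve a [correlation_curve()].
#' @param type `"dynamic"` fits sums of exponentials to an
#'   excess-convention dynamic curve; `"fcs"` fits the full composite
#'   model with 1 and 2 dynamic terms (extra arguments passed to
#'   [fit_fcs()]).
#' @param alpha significance threshold of the F-test (default 0.05).
#' @param ... passed to [fit_fcs()] when `type = "fcs"`.
#' @return object of class `model_comparison`: the two fits, their reduced
#'   chi-squares and residual autocorrelations, `F_stat`, `p_value`, and
#'   `preferred`.
#' @export
compare_dynamic_models <- function(curve, type = c("dynamic", "fcs"),
                                   alpha = 0.05, ...) {
  type <- match.arg(type)
  if (type == "dynamic") {
    fit1 <- fit_exp_components(curve, 1L)
    fit2 <- fit_exp_components(curve, 2L)
  } else {
    fit1 <- fit_fcs(curve, n_dyn = 1L, ...)
    fit2 <- fit_fcs(curve, n_dyn = 2L, ...)
  }
  lag1_ac <- function(r) {
    if (length(r) < 3L || sd(r) == 0) return(NA_real_)
    stats::cor(r[-1L], r[-length(r)])
  }
  df1 <- fit1$n_lags - fit1$n_free
  df2 <- fit2$n_lags - fit2$n_free
  ddf <- df1 - df2
  if (!is.null(fit1$chisq) && !is.null(fit2$chisq) && ddf > 0 &&
      df2 > 0 && fit2$chisq > 0) {
    F_stat <- ((fit1$chisq - fit2$chisq) / ddf) / (fit2$chisq / df2)
    p_value <- if (F_stat > 0) pf(F_stat, ddf, df2, lower.tail = FALSE)
               else 1
  } else {
    F_stat <- NA_real_
    p_value <- NA_real_
  }
  preferred <- if (!is.na(p_value) && p_value < alpha) "two_component"
               else "one_component"
  structure(list(fit1 = fit1, fit2 = fit2,
                 redchisq = c(one = fit1$redchisq, two = fit2$redchisq),
                 chisq_ratio = fit1$chisq / fit2$chisq,
                 resid_lag1_ac = c(one = lag1_ac(fit1$residuals),
                                   two = lag1_ac(fit2$residuals)),
                 F_stat = F_stat, p_value = p_value, alpha = alpha,
                 preferred = preferred),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison> red.chi^2 %.3g (1 comp) vs %.3g (2 comp); F = %.3g, p = %.3g -> %s\n",
    x$redchisq[1L], x$redchisq[2L], x$F_stat, x$p_value, x$preferred))
  invisible(x)
}

#' Write a fit report as JSON plus a residuals table
#'
#' @param fit an `fcs_fit` or `dynamic_fit`.
#' @param path JSON output path; a `<path>_residuals.tsv` table is written
#'   alongside.
#' @return the JSON string, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  est <- if (inherits(fit, "dynamic_fit")) {
    list(a_r = fit$a_r, tau_r_s = fit$tau_r_s,
         rates_per_us = if (!is.null(fit$rates))
           list(k_on = fit$rates$k_on_per_us,
                k_off = fit$rates$k_off_per_us,
                convention = fit$rates$convention))
  } else {
    as.list(fit$estimate)
  }
  x <- list(estimates = est, se = as.list(fit$se),
            ci95 = if (!is.null(fit$ci)) apply(fit$ci, 1L, as.list),
            chisq = fit$chisq, redchisq = fit$redchisq,
            converged = fit$converged)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(js, path)
  utils::write.table(data.frame(weighted_residual = fit$residuals),
                     paste0(sub("\\.json$", "", path), "_residuals.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(js)
}
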