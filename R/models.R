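#' Parameters of the composite FCS model
#'
#' Parameter container for the full correlation model
#' \deqn{G(\tau) = \frac{\gamma}{N}\left(1+\frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1+\frac{\tau}{p^2\tau_D}\right)^{-1/2}
#'   \left(1 - A_{ab} e^{-\tau/\tau_{ab}}\right)
#'   \left(1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right)
#'   \left(1 + \sum_r a_r e^{-\tau/\tau_r}\right)}
#' combining translational diffusion through a 3D-Gaussian confocal volume,
#' photon antibunching, triplet blinking, and up to two dynamic quenching
#' (bunching) terms.
#'
#' @param N mean number of particles in the observation volume.
#' @param tau_D_s diffusion time, seconds.
#' @param p ratio of axial to lateral size of the confocal volume; `Inf`
#'   disables the axial factor.
#' @param gamma shape correction factor for the confocal volume, fixed at
#'   `2^-3/2` by default (overridable).
#' @param A_ab,tau_ab_s antibunching amplitude and relaxation time (s).
#' @param T_frac,tau_T_s triplet fraction (in `[0, 1)`) and triplet time (s).
#' @param dyn list of dynamic terms, each `c(a_r = , tau_r_s = )`; 0, 1 or 2
#'   terms.
#' @return object of class `fcs_params`.
#' @export
fcs_params <- function(N = 1, tau_D_s = 51e-6, p = 5, gamma = 2^(-3 / 2),
                       A_ab = 0, tau_ab_s = 2e-9, T_frac = 0,
                       tau_T_s = 2.4e-6, dyn = list()) {
  stop_if_not_scalar_pos(N, "N")
  stop_if_not_scalar_pos(tau_D_s, "tau_D_s")
  stop_if_not_scalar_pos(gamma, "gamma")
  if (!(is.numeric(p) && length(p) == 1L && p > 0)) stop("invalid p")
  if (A_ab < 0) stop("A_ab must be >= 0")
  if (T_frac < 0 || T_frac >= 1) {
    stop("triplet fraction must be in [0, 1); T = 1 divides by zero")
  }
  stop_if_not_scalar_pos(tau_ab_s, "tau_ab_s")
  stop_if_not_scalar_pos(tau_T_s, "tau_T_s")
  if (length(dyn) > 2L) stop("at most two dynamic terms are supported")
  for (d in dyn) {
    if (d[["a_r"]] < 0) stop("dynamic amplitudes must be >= 0")
    stop_if_not_scalar_pos(d[["tau_r_s"]], "tau_r_s")
  }
  structure(list(N = N, tau_D_s = tau_D_s, p = p, gamma = gamma,
                 A_ab = A_ab, tau_ab_s = tau_ab_s, T_frac = T_frac,
                 tau_T_s = tau_T_s, dyn = dyn),
            class = "fcs_params")
}

#' Evaluate the composite FCS model
#'
#' Product of the diffusion, antibunching, triplet and dynamic factors of
#' the model described in [fcs_params()]. The value is the
#' excess-plus-diffusion form (it decays to 0 at large lags because the
#' diffusion factor does; no baseline of 1 is added).
#'
#' @param tau_s lag times, seconds (> 0).
#' @param params an [fcs_params()] object.
#' @return numeric vector of G values.
#' @examples
#' p <- fcs_params(N = 1, tau_D_s = 51e-6)
#' fcs_model(1e-9, p)   # ~ gamma/N = 0.3536 at tau -> 0
#' @export
fcs_model <- function(tau_s, params) {
  stopifnot(inherits(params, "fcs_params"))
  if (any(tau_s <= 0)) stop("tau must be > 0")
  g <- params$gamma / params$N / (1 + tau_s / params$tau_D_s)
  if (is.finite(params$p)) {
    g <- g / sqrt(1 + tau_s / (params$p^2 * params$tau_D_s))
  }
  if (params$A_ab > 0) {
    g <- g * (1 - params$A_ab * exp(-tau_s / params$tau_ab_s))
  }
  if (params$T_frac > 0) {
    g <- g * (1 + params$T_frac / (1 - params$T_frac) *
                exp(-tau_s / params$tau_T_s))
  }
  if (length(params$dyn)) {
    dyn_sum <- 0
    for (d in params$dyn) {
      dyn_sum <- dyn_sum + d[["a_r"]] * exp(-tau_s / d[["tau_r_s"]])
    }
    g <- g * (1 + dyn_sum)
  }
  g
}

#' Single-exponential two-state decay
#'
#' The dynamic part of the quenching correlation,
#' `G_dyn(tau) = a_r * exp(-tau / tau_r)`.
#'
#' @param tau_s lag times, seconds (>= 0).
#' @param a_r amplitude.
#' @param tau_r_s relaxation time, seconds.
#' @return numeric vector.
#' @export
dyn_model <- function(tau_s, a_r, tau_r_s) {
  stop_if_not_scalar_pos(tau_r_s, "tau_r_s")
  if (any(tau_s < 0)) stop("tau must be >= 0")
  a_r * exp(-tau_s / tau_r_s)
}

#' Convert a dynamic amplitude and relaxation time to microscopic rates
#'
#' Inverts the relations `tau_r = 1/(k_on + k_off)` and `a_r = k_off/k_on`,
#' where `k_on` and `k_off` are the rate constants of end-to-end quenching
#' contact formation and dissociation.
#'
#' Two conventions are provided. `"as_printed"` applies the relations
#' exactly as written above (the form rate tables in the PET-FCS
#' literature are reported in). The
#' closed form of a two-state telegraph emitter, however, has correlation
#' amplitude equal to (dark fraction)/(bright fraction) =
#' k_formation/k_dissociation, i.e. the roles of the two rates exchanged;
#' `"telegraph_oracle"` uses that assignment and is the convention under
#' which rates recovered from simulated telegraph signals match the
#' simulator inputs. The discrepancy between the two is a documented
#' property of the conventional relations, not resolved silently.
#'
#' @param a_r dynamic amplitude (> 0).
#' @param tau_r_s relaxation time, seconds.
#' @param convention `"as_printed"` or `"telegraph_oracle"`.
#' @return list with `k_on_per_us` (contact formation) and `k_off_per_us`
#'   (dissociation), in per-microsecond units, plus the inputs and
#'   convention.
#' @examples
#' rates_from_dynamics(0.67, 80.4e-9)  # k_on ~ 7.4, k_off ~ 5.0 us^-1
#' @export
rates_from_dynamics <- function(a_r, tau_r_s,
                                convention = c("as_printed",
                                               "telegraph_oracle")) {
  convention <- match.arg(convention)
  if (!(is.numeric(a_r) && length(a_r) == 1L && a_r > 0)) {
    stop("a_r must be a single positive number")
  }
  stop_if_not_scalar_pos(tau_r_s, "tau_r_s")
  k_sum <- 1 / tau_r_s * .us  # per microsecond
  if (convention == "as_printed") {
    k_on <- k_sum / (1 + a_r)
    k_off <- a_r * k_on
  } else {
    # amplitude = k_formation / k_dissociation
    k_off <- k_sum / (1 + a_r)
    k_on <- a_r * k_off
  }
  list(k_on_per_us = k_on, k_off_per_us = k_off, a_r = a_r,
       tau_r_s = tau_r_s, convention = convention)
}

#' @rdname rates_from_dynamics
#' @param k_on_per_us,k_off_per_us microscopic contact formation and
#'   dissociation rates, per microsecond.
#' @return for `dynamics_from_rates`, a list with `a_r`, `tau_r_s` and the
#'   convention; the round trip with [rates_from_dynamics()] is the
#'   identity to machine precision.
#' @export
dynamics_from_rates <- function(k_on_per_us, k_off_per_us,
                                convention = c("as_printed",
                                               "telegraph_oracle")) {
  convention <- match.arg(convention)
  stop_if_not_scalar_pos(k_on_per_us, "k_on_per_us")
  stop_if_not_scalar_pos(k_off_per_us, "k_off_per_us")
  tau_r_s <- 1 / (k_on_per_us + k_off_per_us) * .us
  a_r <- if (convention == "as_printed") k_off_per_us / k_on_per_us
         else k_on_per_us / k_off_per_us
  list(a_r = a_r, tau_r_s = tau_r_s, convention = convention)
}

#' Isolate the dynamic part of a correlation curve
#'
#' Divides a fitted correlation curve by the non-dynamic contributions
#' (the gamma/N prefactor, diffusion, antibunching and triplet factors of
#' the composite model) and subtracts 1, leaving the pure dynamic part
#' `sum_r a_r exp(-tau/tau_r)` in the excess convention. Per-lag
#' uncertainties are propagated through the same division.
#'
#' @param curve a [correlation_curve()] in the raw-at-unity sense of the
#'   composite model, i.e. its values decay to 0 like the model itself
#'   (pass excess-convention experimental curves through
#'   [convert_convention()] as needed, or curves already on the model
#'   scale).
#' @param params an [fcs_params()] holding the fitted non-dynamic
#'   parameters; any `dyn` terms in it are ignored.
#' @return an excess-convention [correlation_curve()].
#' @export
isolate_dynamic <- function(curve, params) {
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(params, "fcs_params"))
  base <- params
  base$dyn <- list()
  denom <- fcs_model(curve$lag_s, base)
  if (any(denom <= 0)) {
    stop("non-dynamic model factor is <= 0 at some lag ",
         "(antibunching amplitude >= 1 region): cannot divide")
  }
  vals <- curve$value / denom - 1
  sigma <- if (is.null(curve$sigma)) NULL else curve$sigma / denom
  correlation_curve(curve$lag_s, vals, sigma = sigma,
                    convention = "excess", n_pairs = curve$n_pairs,
                    settings = c(curve$settings, list(isolated = TRUE)))
}

#' Confocal focal geometry and the diffusion coefficient
#'
#' Relates the diffusion time to the diffusion coefficient through the
#' lateral 1/e^2 size of the focal volume: `D = w^2 / (4 tau_D)`.
#'
#' @param w_nm lateral focal size, nm (e.g. 195 nm).
#' @param tau_D_us diffusion time, microseconds.
#' @return diffusion coefficient in um^2/s.
#' @examples
#' diffusion_coefficient(195, 51)  # ~ 186 um^2/s
#' @export
diffusion_coefficient <- function(w_nm, tau_D_us) {
  stop_if_not_scalar_pos(w_nm, "w_nm")
  stop_if_not_scalar_pos(tau_D_us, "tau_D_us")
  (w_nm * 1e-3)^2 / (4 * tau_D_us * 1e-6)  # um^2 / s
}

#' @rdname diffusion_coefficient
#' @param D_um2_s diffusion coefficient, um^2/s.
#' @return for `diffusion_time_us`, the diffusion time `w^2/(4D)` in
#'   microseconds; the round trip with [diffusion_coefficient()] is the
#'   identity.
#' @export
diffusion_time_us <- function(w_nm, D_um2_s) {
  stop_if_not_scalar_pos(w_nm, "w_nm")
  stop_if_not_scalar_pos(D_um2_s, "D_um2_s")
  (w_nm * 1e-3)^2 / (4 * D_um2_s) * 1e6
}

#' Combine two dynamic components into a total amplitude and average time
#'
#' For two-component dynamic fits, reports the sum of the kinetic
#' amplitudes and the average relaxation time of the two components. The
#' default average is amplitude-weighted,
#' `(a1 tau1 + a2 tau2)/(a1 + a2)`; an unweighted arithmetic mean is
#' available by flag.
#'
#' @param a1,tau1_s,a2,tau2_s amplitudes (>= 0, not both zero) and
#'   relaxation times (s) of the two components.
#' @param weights `"amplitude"` (default) or `"arithmetic"`.
#' @return list with `a_total` and `tau_avg_s`.
#' @examples
#' combine_two_component(0.4, 40e-9, 0.27, 140e-9)  # a 0.67, tau ~ 80.3 ns
#' @export
combine_two_component <- function(a1, tau1_s, a2, tau2_s,
                                  weights = c("amplitude", "arithmetic")) {
  weights <- match.arg(weights)
  if (a1 < 0 || a2 < 0) stop("amplitudes must be >= 0")
  if (a1 + a2 == 0) stop("both amplitudes are zero")
  tau_avg <- if (weights == "amplitude") {
    (a1 * tau1_s + a2 * tau2_s) / (a1 + a2)
  } else {
    (tau1_s + tau2_s) / 2
  }
  # a degenerate (zero-amplitude) component contributes no time
  if (a1 == 0) tau_avg <- if (weights == "amplitude") tau2_s else tau_avg
  if (a2 == 0) tau_avg <- if (weights == "amplitude") tau1_s else tau_avg
  list(a_total = a1 + a2, tau_avg_s = tau_avg)
}

#' Serialize model parameters to JSON with explicit units
#'
#' @param params an [fcs_params()].
#' @param path optional output path; if omitted the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to file.
#' @export
write_fcs_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "fcs_params"))
  x <- list(N = params$N, tau_D_s = params$tau_D_s, p = params$p,
            gamma = params$gamma, A_ab = params$A_ab,
            tau_ab_s = params$tau_ab_s, T_frac = params$T_frac,
            tau_T_s = params$tau_T_s,
            dyn = lapply(params$dyn, as.list))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
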