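#' Photon arrival-time stream
#'
#' Ordered photon arrival timestamps on one or two detection channels, as
#' integer multiples of the recording tick. Identical quantized timestamps
#' on one channel are merged (a detector cannot register two photons in one
#' tick), so per-channel timestamps are strictly increasing.
#'
#' @param tick numeric vector of integer-valued tick indices (doubles are
#'   used because streams of seconds at picosecond resolution exceed the
#'   32-bit integer range).
#' @param channel integer channel per photon (1 or 2).
#' @param tick_ps tick resolution, picoseconds (e.g. 16 ps).
#' @param duration_s total recorded duration, seconds.
#' @param truth optional generator ground truth.
#' @return object of class `photon_stream`.
#' @export
photon_stream <- function(tick, channel, tick_ps, duration_s, truth = NULL) {
  stop_if_not_scalar_pos(tick_ps, "tick_ps")
  stop_if_not_scalar_pos(duration_s, "duration_s")
  if (length(tick) != length(channel)) stop("tick/channel length mismatch")
  o <- order(tick, channel)
  tick <- tick[o]; channel <- as.integer(channel[o])
  keep <- !duplicated(data.frame(tick, channel))
  tick <- tick[keep]; channel <- channel[keep]
  for (ch in unique(channel)) {
    tc <- tick[channel == ch]
    if (length(tc) > 1L && any(diff(tc) <= 0)) {
      stop("per-channel timestamps must be strictly increasing")
    }
  }
  structure(list(tick = tick, channel = channel, tick_ps = tick_ps,
                 duration_s = duration_s, truth = truth),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf(
    "<photon_stream> %d photons, %d channel(s), tick %g ps, %.4g s (%.3g kcps)\n",
    length(x$tick), length(unique(x$channel)), x$tick_ps, x$duration_s,
    length(x$tick) / x$duration_s / 1000))
  invisible(x)
}

#' Parameters of the confocal photon-stream simulator
#'
#' Generative model: point emitters diffuse by Brownian steps in a periodic
#' box around a 3D-Gaussian detection volume; the instantaneous emission
#' rate of particle `i` is `brightness * W(x_i)` with
#' `W = exp(-2x^2/w^2 - 2y^2/w^2 - 2z^2/(p w)^2)`, multiplied by binary
#' triplet and quenching telegraph factors. Photons are drawn by
#' inhomogeneous Poisson thinning. The diffusion intensity is held constant
#' within one Brownian step; the binary triplet/quench factors are evaluated
#' *exactly* at the proposed photon times from the two-state Markov
#' transition probabilities, so the Brownian step only needs to resolve the
#' diffusion time (guard: `dt_sim <= tau_D / 10`).
#'
#' `N` is the mean number of particles in the observation volume
#' `V_obs = (pi/2)^(3/2) w^3 p` (equivalently, the mean total detection
#' weight), which is the `N` of the composite FCS model with
#' `gamma = 2^-3/2`.
#'
#' @param N mean number of particles in the observation volume.
#' @param w_nm lateral 1/e^2 focal radius, nm.
#' @param p axial-to-lateral ratio of the focal volume.
#' @param D_um2_s diffusion coefficient, um^2/s (0 = immobile particles).
#' @param brightness_cps detected photon rate of one particle at the focus
#'   center, counts per second.
#' @param T_frac,tau_T_us triplet fraction in `[0, 1)` and triplet
#'   relaxation time in us (`T_frac = 0` disables triplet blinking).
#' @param quench optional [telegraph_params()]-style list with elements
#'   `k_form` and `k_diss` (per us) for per-particle quenching dynamics.
#' @param excited_lifetime_ns optional excited-state lifetime for
#'   antibunching: after each emitted photon the next photon of that
#'   particle is delayed by an exponential excited-state dwell.
#' @param duration_s simulated duration, seconds.
#' @param tick_ps timestamp quantization, ps.
#' @param split if `TRUE`, photons are split 50:50 at random onto two
#'   channels (beam-splitter arrangement); otherwise a single channel.
#' @param box_lateral_w,box_axial_pw periodic box size as multiples of the
#'   lateral (w) and axial (p w) focal radii. In a periodic box the
#'   correlation decays to baseline at the box mixing time
#'   (`~(L/(2 pi))^2 / D` for the slowest mode) instead of following the
#'   open-space power-law tail; the defaults put that time well beyond
#'   `10 tau_D` laterally. Image weights are negligible at any usable
#'   size.
#' @param dt_sim_s Brownian step; default `tau_D / 100`, refused if larger
#'   than `tau_D / 10`.
#' @param coarse_factor particles sitting where the detection weight is
#'   below the emission threshold advance this many Brownian steps at once
#'   (exact Gaussian marginal, no emission there); capped so one coarse
#'   displacement stays below `0.35 w`. Set 1 to disable.
#' @param positions_nm optional fixed initial positions (n x 3 matrix, nm),
#'   mainly for placing an immobile emitter at the focus center.
#' @param seed integer seed.
#' @return object of class `photon_sim_params`.
#' @export
photon_sim_params <- function(N = 1, w_nm = 195, p = 5, D_um2_s = 185,
                              brightness_cps = 2.5e5, T_frac = 0,
                              tau_T_us = 2.4, quench = NULL,
                              excited_lifetime_ns = NULL,
                              duration_s = 0.1, tick_ps = 16, split = TRUE,
                              box_lateral_w = 12, box_axial_pw = 6,
                              dt_sim_s = NULL, positions_nm = NULL,
                              coarse_factor = 16L, seed = 1L) {
  stop_if_not_scalar_pos(N, "N")
  stop_if_not_scalar_pos(w_nm, "w_nm")
  stop_if_not_scalar_pos(p, "p")
  if (D_um2_s < 0) stop("D_um2_s must be >= 0")
  stop_if_not_scalar_pos(brightness_cps, "brightness_cps")
  if (T_frac < 0 || T_frac >= 1) stop("T_frac must be in [0, 1)")
  stop_if_not_scalar_pos(tau_T_us, "tau_T_us")
  if (!is.null(quench)) {
    stop_if_not_scalar_pos(quench$k_form, "quench$k_form")
    stop_if_not_scalar_pos(quench$k_diss, "quench$k_diss")
  }
  if (!is.null(excited_lifetime_ns)) {
    stop_if_not_scalar_pos(excited_lifetime_ns, "excited_lifetime_ns")
  }
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stop_if_not_scalar_pos(tick_ps, "tick_ps")
  structure(list(N = N, w_nm = w_nm, p = p, D_um2_s = D_um2_s,
                 brightness_cps = brightness_cps, T_frac = T_frac,
                 tau_T_us = tau_T_us, quench = quench,
                 excited_lifetime_ns = excited_lifetime_ns,
                 duration_s = duration_s, tick_ps = tick_ps, split = split,
                 box_lateral_w = box_lateral_w, box_axial_pw = box_axial_pw,
                 dt_sim_s = dt_sim_s, positions_nm = positions_nm,
                 coarse_factor = as.integer(coarse_factor),
                 seed = as.integer(seed)),
            class = "photon_sim_params")
}

# Exact state of a two-state Markov process at increasing times.
# pi1 = stationary probability of state 1; k = sum of the two rates (s^-1).
# Returns 0/1 vector. Sequential because each state conditions the next.
markov_state_at_times <- function(times, pi1, k) {
  n <- length(times)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  u <- runif(n)
  decay <- exp(-k * diff(c(0, times)))
  s <- as.integer(u[1] < pi1)  # stationary initial state at the first time
  out[1] <- s
  if (n > 1L) {
    for (i in 2:n) {
      s <- as.integer(u[i] < pi1 + (s - pi1) * decay[i])
      out[i] <- s
    }
  }
  out
}

#' Simulate a confocal photon stream
#'
#' Runs the generative model described in [photon_sim_params()]. The
#' correlation of the resulting stream follows the composite FCS model:
#' diffusion with `tau_D = w^2/(4D)`, triplet factor `(1 + T/(1-T)
#' exp(-tau/tau_T))`, quenching factor `(1 + (k_form/k_diss)
#' exp(-(k_form+k_diss) tau))`, and an antibunching dip when an excited
#' lifetime is set.
#'
#' @param params a [photon_sim_params()] object.
#' @return a [photon_stream()] whose `truth` records the realized particle
#'   number, `tau_D`, and all generative parameters.
#' @export
simulate_photons <- function(params) {
  stopifnot(inherits(params, "photon_sim_params"))
  set.seed(params$seed)
  w <- params$w_nm * 1e-3                      # um
  p <- params$p
  D <- params$D_um2_s
  tau_D <- if (D > 0) w^2 / (4 * D) else Inf   # s
  dt <- params$dt_sim_s
  if (is.null(dt)) dt <- if (is.finite(tau_D)) tau_D / 100 else
    params$duration_s / 1e4
  if (is.finite(tau_D) && dt > tau_D / 10) {
    stop("resolution guard: dt_sim_s = ", signif(dt, 3),
         " s exceeds tau_D / 10 = ", signif(tau_D / 10, 3),
         " s; the Brownian step must resolve the diffusion time")
  }
  L <- c(params$box_lateral_w * w, params$box_lateral_w * w,
         params$box_axial_pw * p * w)          # box side lengths, um
  V_obs <- (pi / 2)^(3 / 2) * w^3 * p
  if (is.null(params$positions_nm)) {
    n_part <- max(1L, as.integer(round(params$N * prod(L) / V_obs)))
    pos0 <- cbind(runif(n_part, -L[1] / 2, L[1] / 2),
                  runif(n_part, -L[2] / 2, L[2] / 2),
                  runif(n_part, -L[3] / 2, L[3] / 2))
  } else {
    pos0 <- matrix(params$positions_nm * 1e-3, ncol = 3)
    n_part <- nrow(pos0)
  }
  N_realized <- n_part * V_obs / prod(L)
  n_steps <- ceiling(params$duration_s / dt)
  sigma_step <- sqrt(2 * D * dt)               # per-axis displacement, um
  tau_T <- params$tau_T_us * .us
  has_triplet <- params$T_frac > 0
  if (has_triplet) {
    k_T <- 1 / tau_T                           # sum of triplet rates
    pi_singlet <- 1 - params$T_frac
  }
  qp <- params$quench
  has_quench <- !is.null(qp)
  if (has_quench) {
    k_Q <- (qp$k_form + qp$k_diss) / .us
    pi_bright <- qp$k_diss / (qp$k_form + qp$k_diss)
  }
  w2 <- w^2
  wz2 <- (p * w)^2
  # coarse-step factor capped so one coarse displacement stays well below
  # the distance from the emission threshold shell to appreciable weight
  coarse <- if (sigma_step > 0) {
    max(1L, min(params$coarse_factor,
                floor((0.35 * w / sigma_step)^2)))
  } else 1L
  prop <- photon_proposals_cpp(pos0, as.integer(n_steps), dt, sigma_step,
                               L, w2, wz2, params$brightness_cps, 1e-6,
                               as.integer(coarse))
  by_particle <- split(prop$time_s, prop$particle)
  all_times <- vector("list", length(by_particle))
  for (ip in seq_along(by_particle)) {
    t_prop <- sort(by_particle[[ip]])
    t_prop <- t_prop[t_prop < params$duration_s]
    if (has_quench && length(t_prop)) {
      t_prop <- t_prop[markov_state_at_times(t_prop, pi_bright, k_Q) == 1L]
    }
    if (has_triplet && length(t_prop)) {
      t_prop <- t_prop[markov_state_at_times(t_prop, pi_singlet, k_T) == 1L]
    }
    if (!is.null(params$excited_lifetime_ns) && length(t_prop) > 1L) {
      tl <- params$excited_lifetime_ns * .ns
      keep <- logical(length(t_prop))
      t_last <- -Inf
      for (i in seq_along(t_prop)) {
        if (t_prop[i] >= t_last) {
          keep[i] <- TRUE
          t_last <- t_prop[i] + rexp(1L, 1 / tl)
        }
      }
      t_prop <- t_prop[keep]
    }
    all_times[[ip]] <- t_prop
  }
  t_all <- sort(unlist(all_times))
  if (length(t_all) == 0L) {
    stop("no photons generated; increase brightness or duration")
  }
  channel <- if (isTRUE(params$split)) {
    sample(c(1L, 2L), length(t_all), replace = TRUE)
  } else rep(1L, length(t_all))
  tick <- floor(t_all / (params$tick_ps * .ps))
  photon_stream(tick, channel, params$tick_ps, params$duration_s,
                truth = list(params = params, n_particles_box = n_part,
                             N_realized = N_realized, tau_D_s = tau_D,
                             dt_sim_s = dt,
                             a_r_telegraph = if (has_quench)
                               qp$k_form / qp$k_diss else NULL,
                             tau_r_s = if (has_quench) 1 / k_Q else NULL))
}

#' Write / read a photon stream as delimited text
#'
#' Two-column text (`channel`, `tick`) with a header line recording the
#' tick resolution and duration.
#'
#' @param stream a [photon_stream()].
#' @param path file path.
#' @export
write_photons <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# petfcs photon_stream tick_ps=%.10g duration_s=%.10g",
                     stream$tick_ps, stream$duration_s), con)
  write.table(data.frame(channel = stream$channel,
                         tick = format(stream$tick, scientific = FALSE,
                                       trim = TRUE)),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_photons
#' @return for `read_photons`, the reconstructed [photon_stream()].
#' @export
read_photons <- function(path) {
  hdr <- readLines(path, n = 1L)
  tick_ps <- as.numeric(sub(".*tick_ps=(\\S+).*", "\\1", hdr))
  duration_s <- as.numeric(sub(".*duration_s=(\\S+).*", "\\1", hdr))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("integer", "numeric"))
  photon_stream(df$tick, df$channel, tick_ps, duration_s)
}
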