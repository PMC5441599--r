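#' Uniformly sampled discrete-state series
#'
#' Container for a binary (bright/dark) or ternary (open/intermediate/close)
#' state series sampled on a uniform time grid, as produced by the telegraph
#' simulator or by classifying trajectory frames.
#'
#' @param values integer or character vector of states. Binary series use
#'   `1` = fluorescent (bright) and `0` = dark; ternary series use the labels
#'   `"open"`, `"intermediate"`, `"close"`.
#' @param dt_s sampling interval in seconds.
#' @param kind `"binary"` or `"ternary"`.
#' @param truth optional list of ground-truth generator information (hidden
#'   transition counts, rates, jump times) attached by simulators.
#'
#' @return An object of class `state_sequence`: a list with elements
#'   `values`, `dt_s`, `kind`, `truth`.
#' @export
state_sequence <- function(values, dt_s, kind = c("binary", "ternary"),
                           truth = NULL) {
  kind <- match.arg(kind)
  stop_if_not_scalar_pos(dt_s, "dt_s")
  if (kind == "binary") {
    if (!all(values %in% c(0, 1))) {
      stop("binary state_sequence values must be 0 (dark) or 1 (fluorescent)")
    }
    values <- as.integer(values)
  } else {
    if (!all(values %in% c("open", "intermediate", "close"))) {
      stop("ternary state_sequence values must be 'open', 'intermediate' or 'close'")
    }
    values <- as.character(values)
  }
  structure(list(values = values, dt_s = dt_s, kind = kind, truth = truth),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %s, %d samples, dt = %g ns, duration = %g us\n",
              x$kind, length(x$values), x$dt_s / .ns,
              length(x$values) * x$dt_s / .us))
  if (x$kind == "binary") {
    cat(sprintf("  bright fraction: %.4f\n", mean(x$values)))
  } else {
    tb <- table(factor(x$values, levels = c("open", "intermediate", "close")))
    cat("  ", paste(sprintf("%s: %.1f%%", names(tb), 100 * tb / sum(tb)),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Duration of a state sequence in seconds
#' @param x a `state_sequence`.
#' @return total sampled duration `length(values) * dt_s` in seconds.
#' @export
duration_s <- function(x) length(x$values) * x$dt_s

#' Parameters of a two-state (telegraph) quenching process
#'
#' The continuous-time two-state Markov process underlying the dark /
#' fluorescent classification: `k_form` is the rate of quenching-contact
#' formation (bright to dark), `k_diss` the dissociation rate (dark to
#' bright). The stationary bright fraction is `k_diss / (k_form + k_diss)`
#' and the normalized intensity autocorrelation is
#' `1 + (k_form / k_diss) * exp(-(k_form + k_diss) * tau)`.
#'
#' @param k_form contact-formation rate (bright to dark), per microsecond.
#' @param k_diss contact-dissociation rate (dark to bright), per microsecond.
#' @param dt_ns sampling interval of the output grid, nanoseconds.
#' @param n_steps number of samples to generate.
#' @param seed integer seed for reproducibility.
#' @return A list of class `telegraph_params`.
#' @export
telegraph_params <- function(k_form, k_diss, dt_ns = 30, n_steps = 1e6,
                             seed = 1L) {
  stop_if_not_scalar_pos(k_form, "k_form")
  stop_if_not_scalar_pos(k_diss, "k_diss")
  stop_if_not_scalar_pos(dt_ns, "dt_ns")
  stop_if_not_scalar_pos(n_steps, "n_steps")
  structure(list(k_form = k_form, k_diss = k_diss, dt_ns = dt_ns,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "telegraph_params")
}

# Event-driven jump times of a two-state Markov process over [0, t_end].
# Returns list(jumps = times of state changes (s), state0 = initial state)
# where state 1 = bright, 0 = dark. Rates in s^-1.
simulate_telegraph_events <- function(k_bd, k_db, t_end, state0 = NULL) {
  if (is.null(state0)) {
    state0 <- as.integer(runif(1) < k_db / (k_bd + k_db)) # stationary draw
  }
  jumps <- numeric(0)
  t <- 0
  s <- state0
  # draw dwell times in blocks to limit R-level looping
  repeat {
    n_guess <- max(16L, ceiling((t_end - t) * (k_bd + k_db) * 1.5))
    for (i in seq_len(n_guess)) {
      rate <- if (s == 1L) k_bd else k_db
      t <- t + rexp(1L, rate)
      if (t >= t_end) return(list(jumps = jumps, state0 = state0))
      jumps <- c(jumps, t)
      s <- 1L - s
    }
  }
}

# State of the process at arbitrary times, given its jump times.
telegraph_state_at <- function(times, jumps, state0) {
  n_before <- findInterval(times, jumps)
  as.integer((state0 + n_before) %% 2L)
}

#' Simulate a two-state telegraph quenching signal
#'
#' Exact continuous-time simulation (event-driven exponential dwell times,
#' initial state drawn from the stationary distribution) subsequently sampled
#' on a uniform grid, mimicking the per-frame dark / fluorescent
#' classification of an MD trajectory.
#'
#' @param params a [telegraph_params()] object.
#' @return A binary [state_sequence()] (1 = fluorescent, 0 = dark) with
#'   `truth` carrying the generative rates, the exact jump times, and the
#'   hidden transition count.
#' @examples
#' s <- simulate_telegraph(telegraph_params(5, 5, dt_ns = 1, n_steps = 1e4))
#' mean(s$values)  # close to 0.5
#' @export
simulate_telegraph <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  set.seed(params$seed)
  dt <- params$dt_ns * .ns
  k_bd <- params$k_form / .us   # bright -> dark, s^-1
  k_db <- params$k_diss / .us   # dark -> bright, s^-1
  t_end <- params$n_steps * dt
  ev <- simulate_telegraph_events(k_bd, k_db, t_end)
  grid <- (seq_len(params$n_steps) - 1L) * dt
  vals <- telegraph_state_at(grid, ev$jumps, ev$state0)
  state_sequence(vals, dt, "binary",
                 truth = list(k_form = params$k_form, k_diss = params$k_diss,
                              jumps_s = ev$jumps, state0 = ev$state0,
                              n_hidden_transitions = length(ev$jumps),
                              bright_fraction = k_db / (k_bd + k_db)))
}

#' Simulate a two-well end-to-end distance trajectory
#'
#' Piecewise-constant hidden two-state process (wells at `d_close_nm` and
#' `d_open_nm`, symmetric-rate or asymmetric hopping) observed with Gaussian
#' noise, emulating the C-beta end-to-end distance of a peptide switching
#' between a compact and an extended regime.
#'
#' By default the wells are required to clear the regime thresholds
#' (1.3 nm / 2.5 nm) by three noise standard deviations so that regime
#' assignment is unambiguous; wells inside the intermediate band trigger a
#' warning, not an error.
#'
#' @param d_close_nm distance of the compact well, nm.
#' @param d_open_nm distance of the extended well, nm.
#' @param hop_rates per-direction hopping rates, per microsecond; length 1
#'   (symmetric) or 2 (`close->open`, `open->close`).
#' @param noise_sd_nm Gaussian observation noise, nm.
#' @param dt_ns sampling interval, ns.
#' @param n_steps number of frames.
#' @param seed integer seed.
#' @param d_close_thresh_nm,d_open_thresh_nm regime thresholds used for the
#'   separability warning (defaults 1.3 and 2.5 nm).
#' @return list of class `two_well_series` with `distance_nm` (per-frame
#'   observed distance), `dt_s`, `hidden` (a ternary [state_sequence()] of
#'   the noiseless regime), and `truth` (hidden transition count and rates).
#' @export
simulate_two_well_distance <- function(d_close_nm, d_open_nm, hop_rates,
                                       noise_sd_nm = 0.05, dt_ns = 30,
                                       n_steps = 1e5, seed = 1L,
                                       d_close_thresh_nm = 1.3,
                                       d_open_thresh_nm = 2.5) {
  stop_if_not_scalar_pos(d_close_nm, "d_close_nm")
  stop_if_not_scalar_pos(d_open_nm, "d_open_nm")
  if (d_close_nm >= d_open_nm) stop("d_close_nm must be < d_open_nm")
  if (length(hop_rates) == 1L) hop_rates <- rep(hop_rates, 2L)
  if (any(hop_rates < 0)) stop("hop_rates must be non-negative")
  if (noise_sd_nm < 0) stop("noise_sd_nm must be >= 0")
  if (d_close_nm > d_close_thresh_nm - 3 * noise_sd_nm ||
      d_open_nm < d_open_thresh_nm + 3 * noise_sd_nm) {
    warning("wells are within 3 noise SD of the intermediate band; ",
            "regime assignment may be ambiguous")
  }
  set.seed(seed)
  dt <- dt_ns * .ns
  t_end <- n_steps * dt
  k_co <- hop_rates[1] / .us  # close -> open
  k_oc <- hop_rates[2] / .us  # open  -> close
  if (k_co == 0 && k_oc == 0) {
    ev <- list(jumps = numeric(0), state0 = 1L)
  } else if (k_co == 0 || k_oc == 0) {
    # absorbing: at most one jump out of the non-absorbing state
    state0 <- as.integer(runif(1) < 0.5)
    rate0 <- if (state0 == 1L) k_co else k_oc
    jumps <- if (rate0 > 0) { j <- rexp(1L, rate0); j[j < t_end] } else numeric(0)
    ev <- list(jumps = jumps, state0 = state0)
  } else {
    ev <- simulate_telegraph_events(k_co, k_oc, t_end)  # 1 = close, 0 = open
  }
  grid <- (seq_len(n_steps) - 1L) * dt
  in_close <- telegraph_state_at(grid, ev$jumps, ev$state0) == 1L
  d <- ifelse(in_close, d_close_nm, d_open_nm)
  if (noise_sd_nm > 0) d <- d + rnorm(n_steps, sd = noise_sd_nm)
  hidden <- state_sequence(ifelse(in_close, "close", "open"), dt, "ternary")
  structure(list(distance_nm = d, dt_s = dt, hidden = hidden,
                 truth = list(n_hidden_jumps = length(ev$jumps),
                              n_hidden_sampled = sum(diff(in_close) != 0L),
                              hop_rates_per_us = hop_rates,
                              jumps_s = ev$jumps)),
            class = "two_well_series")
}

#' Write / read a sampled series as two-column delimited text
#'
#' Plain-text interchange for state sequences and distance series:
#' `time_s<TAB>value` with a `#`-prefixed header line recording the sampling
#' interval.
#'
#' @param x a `state_sequence` or `two_well_series`.
#' @param path output file.
#' @export
write_series <- function(x, path) {
  if (inherits(x, "state_sequence")) {
    vals <- x$values; dt <- x$dt_s; kind <- x$kind
  } else if (inherits(x, "two_well_series")) {
    vals <- x$distance_nm; dt <- x$dt_s; kind <- "distance_nm"
  } else stop("unsupported series type")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# petfcs series kind=%s dt_s=%.12g", kind, dt), con)
  write.table(data.frame(time_s = (seq_along(vals) - 1) * dt, value = vals),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_series
#' @param path input file written by [write_series()].
#' @return for `read_series`, a list with `time_s`, `value`, `dt_s`, `kind`.
#' @export
read_series <- function(path) {
  hdr <- readLines(path, n = 1L)
  kind <- sub(".*kind=(\\S+).*", "\\1", hdr)
  dt <- as.numeric(sub(".*dt_s=(\\S+).*", "\\1", hdr))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(time_s = df$time_s, value = df$value, dt_s = dt, kind = kind)
}
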