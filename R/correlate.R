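#' Normalized intensity correlation curve
#'
#' Second-order intensity correlation values on a lag grid, in either the
#' raw convention (G -> 1 at large lags) or excess convention (G -> 0;
#' conversion between the two is subtraction of exactly 1).
#'
#' @param lag_s strictly increasing positive lag times, seconds.
#' @param value correlation values G(tau).
#' @param sigma optional per-lag standard errors (>= 0).
#' @param convention `"raw"` or `"excess"`.
#' @param n_pairs optional number of contributing products per lag.
#' @param settings optional list of correlator settings (recorded in file
#'   headers).
#' @return object of class `correlation_curve`.
#' @export
correlation_curve <- function(lag_s, value, sigma = NULL,
                              convention = c("raw", "excess"),
                              n_pairs = NULL, settings = NULL) {
  convention <- match.arg(convention)
  if (any(lag_s <= 0) || any(diff(lag_s) <= 0)) {
    stop("lags must be strictly increasing and positive")
  }
  if (length(value) != length(lag_s)) stop("value/lag length mismatch")
  if (!is.null(sigma)) {
    if (length(sigma) != length(lag_s) || any(sigma < 0, na.rm = TRUE)) {
      stop("sigma must be per-lag and non-negative")
    }
  }
  structure(list(lag_s = as.numeric(lag_s), value = as.numeric(value),
                 sigma = sigma, convention = convention,
                 n_pairs = n_pairs, settings = settings),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d lags [%.3g, %.3g] s, %s convention%s\n",
              length(x$lag_s), min(x$lag_s), max(x$lag_s), x$convention,
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(lag_s = x$lag_s, G = x$value,
             sigma = if (is.null(x$sigma)) NA_real_ else x$sigma)
}

#' Convert a correlation curve between raw and excess conventions
#' @param curve a [correlation_curve()].
#' @param to target convention.
#' @return the converted curve (unchanged if already in `to`).
#' @export
convert_convention <- function(curve, to = c("excess", "raw")) {
  to <- match.arg(to)
  if (curve$convention == to) return(curve)
  shift <- if (to == "excess") -1 else 1
  correlation_curve(curve$lag_s, curve$value + shift, curve$sigma, to,
                    curve$n_pairs, curve$settings)
}

#' Direct evaluation of the intensity correlation function
#'
#' Brute-force time-average estimator of
#' `G(tau) = <I(t) I(t + tau)> / (<I(t)> <I(t + tau)>)` on a uniformly
#' sampled signal, with symmetric normalization: the two means in the
#' denominator are taken over the overlapping windows at each lag, which
#' removes the linear finite-length bias. Serves as the exact reference the
#' multiple-tau correlator is checked against.
#'
#' @param signal numeric intensity series (or binary 0/1 quench signal),
#'   uniformly sampled.
#' @param lags integer lag indices (multiples of `dt_s`), all `>= 1` and
#'   `< length(signal)`.
#' @param dt_s sampling interval, seconds.
#' @return a raw-convention [correlation_curve()] with `n_pairs` recording
#'   the number of contributing products per lag.
#' @export
direct_correlation <- function(signal, lags, dt_s) {
  stop_if_not_scalar_pos(dt_s, "dt_s")
  lags <- sort(unique(as.integer(lags)))
  n <- length(signal)
  if (any(lags < 1L)) stop("lags must be >= 1 sample")
  if (max(lags) >= n) stop("signal length must exceed the maximum lag")
  if (mean(signal) == 0) stop("zero-mean signal: normalization undefined")
  vals <- numeric(length(lags))
  npair <- integer(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    a <- signal[seq_len(n - k)]
    b <- signal[seq.int(k + 1L, n)]
    ma <- mean(a); mb <- mean(b)
    if (ma == 0 || mb == 0) stop("window mean is zero at lag ", k,
                                 ": normalization undefined")
    vals[i] <- mean(a * b) / (ma * mb)
    npair[i] <- n - k
  }
  correlation_curve(lags * dt_s, vals, convention = "raw", n_pairs = npair,
                    settings = list(correlator = "direct", dt_s = dt_s))
}

#' Quasi-logarithmic lag indices
#'
#' Integer lag subset with approximately `n_per_decade` points per decade,
#' used to evaluate the direct correlator of long binary MD signals on a
#' logarithmic grid.
#'
#' @param max_lag largest lag index.
#' @param n_per_decade points per decade.
#' @return sorted unique integer lags from 1 to `max_lag`.
#' @export
log_lags <- function(max_lag, n_per_decade = 16) {
  raw <- 10^seq(0, log10(max_lag), by = 1 / n_per_decade)
  sort(unique(pmin(as.integer(round(raw)), as.integer(max_lag))))
}

# Bin one channel of a photon stream into counts at bin_s resolution.
bin_photons <- function(stream, channel, bin_s, t0_s = 0,
                        duration_s = NULL) {
  t <- stream$tick[stream$channel == channel] * stream$tick_ps * .ps
  if (is.null(duration_s)) duration_s <- stream$duration_s - t0_s
  t <- t[t >= t0_s & t < t0_s + duration_s]
  n_bins <- ceiling(duration_s / bin_s)
  if (n_bins < 1L) stop("empty binning window")
  idx <- floor((t - t0_s) / bin_s) + 1
  idx[idx > n_bins] <- n_bins
  tabulate(idx, nbins = n_bins)
}

# Multiple-tau engine on two binned count/intensity series (same base bin).
# Level 0: lags 1..m at base_bin; each further level halves the sampling
# rate (pairwise sums) and evaluates lags m/2+1 .. m.
#
# Normalization: symmetric (means over the overlapping windows, as in
# direct_correlation) by default; when per-base-bin expected counts
# (mu_i, mu_j) are supplied -- e.g. full-measurement rates while
# correlating one segment -- those shared denominators are used instead,
# which removes most of the finite-window normalization bias.
mt_engine <- function(ci, cj, base_bin_s, m, max_lag_s,
                      mu_i = NULL, mu_j = NULL) {
  stopifnot(length(ci) == length(cj))
  shared <- !is.null(mu_i)
  lag_s <- numeric(0); vals <- numeric(0); npair <- numeric(0)
  bin <- base_bin_s
  level <- 0L
  scale <- 1
  repeat {
    n <- length(ci)
    kset <- if (level == 0L) seq_len(m) else seq.int(m / 2 + 1L, m)
    kset <- kset[kset * bin <= max_lag_s & kset < n]
    if (length(kset) == 0L) break
    for (k in kset) {
      a <- ci[seq_len(n - k)]
      b <- cj[seq.int(k + 1L, n)]
      if (shared) {
        denom <- (mu_i * scale) * (mu_j * scale)
        g <- if (denom == 0) NA_real_ else mean(a * b) / denom
      } else {
        ma <- mean(a); mb <- mean(b)
        g <- if (ma == 0 || mb == 0) NA_real_ else mean(a * b) / (ma * mb)
      }
      lag_s <- c(lag_s, k * bin); vals <- c(vals, g)
      npair <- c(npair, n - k)
    }
    # coarsen by 2 for the next level
    if (n < 2L * m + 2L || (m * 2 * bin) > max_lag_s) break
    n2 <- floor(n / 2) * 2L
    ci <- ci[seq(1, n2, by = 2)] + ci[seq(2, n2, by = 2)]
    cj <- cj[seq(1, n2, by = 2)] + cj[seq(2, n2, by = 2)]
    bin <- bin * 2
    scale <- scale * 2
    level <- level + 1L
  }
  keep <- !is.na(vals)
  list(lag_s = lag_s[keep], value = vals[keep], n_pairs = npair[keep])
}

#' Multiple-tau correlation of a photon stream or sampled signal
#'
#' Correlator with quasi-logarithmic lag spacing: `m` linear lags at the
#' base bin width, then `m/2` lags per level with the bin width doubling
#' each level. Photon timestamps are binned at the current level's width
#' before correlating (the classic multiple-tau scheme); sampled signals
#' use their sampling interval as the base bin.
#'
#' @param x a [photon_stream()] or a numeric sampled intensity series.
#' @param i,j channel indices to correlate (`i == j` gives the
#'   autocorrelation). Ignored for sampled signals.
#' @param m points per level; even, `>= 8` (default 16).
#' @param base_bin_s base bin width in seconds. For photon streams the
#'   default chooses the smallest power-of-two multiple of the tick giving
#'   at most `2^22` bins; required for sampled signals to equal `dt_s`.
#' @param max_lag_s largest lag to evaluate (default: 1/8 of the data
#'   duration).
#' @param dt_s sampling interval when `x` is a numeric series.
#' @param normalization photon streams only: `"shared"` (default) divides
#'   by the full-measurement mean rates, `"symmetric"` by the means over
#'   the overlapping windows at each lag. Sampled signals always use the
#'   symmetric normalization of [direct_correlation()].
#' @return a raw-convention [correlation_curve()].
#' @export
multiple_tau_correlation <- function(x, i = 1L, j = i, m = 16L,
                                     base_bin_s = NULL, max_lag_s = NULL,
                                     dt_s = NULL,
                                     normalization = c("shared",
                                                       "symmetric")) {
  normalization <- match.arg(normalization)
  if (m %% 2L != 0L || m < 8L) stop("m must be even and >= 8")
  if (inherits(x, "photon_stream")) {
    if (length(x$tick) == 0L) stop("empty photon stream")
    if (length(x$tick) == 1L) stop("single photon: correlation undefined")
    if (is.null(base_bin_s)) {
      tick_s <- x$tick_ps * .ps
      k <- max(0, ceiling(log2(x$duration_s / tick_s / 2^22)))
      base_bin_s <- tick_s * 2^k
    }
    if (x$duration_s <= m * base_bin_s) {
      stop("total duration must exceed m * base_bin_s")
    }
    if (is.null(max_lag_s)) max_lag_s <- x$duration_s / 8
    ci <- bin_photons(x, i, base_bin_s)
    cj <- if (j == i) ci else bin_photons(x, j, base_bin_s)
    if (normalization == "shared") {
      eng <- mt_engine(ci, cj, base_bin_s, m, max_lag_s,
                       mu_i = mean(ci), mu_j = mean(cj))
    } else {
      eng <- mt_engine(ci, cj, base_bin_s, m, max_lag_s)
    }
    mode <- if (i == j) "auto" else "cross"
  } else {
    if (is.null(dt_s)) stop("dt_s required for sampled signals")
    if (!is.null(base_bin_s) && abs(base_bin_s - dt_s) > 1e-15 * dt_s) {
      stop("for sampled signals base_bin_s must equal dt_s")
    }
    if (length(x) <= m) stop("signal shorter than m samples")
    if (is.null(max_lag_s)) max_lag_s <- length(x) * dt_s / 8
    eng <- mt_engine(as.numeric(x), as.numeric(x), dt_s, m, max_lag_s)
    base_bin_s <- dt_s
    mode <- "auto"
  }
  correlation_curve(eng$lag_s, eng$value, convention = "raw",
                    n_pairs = eng$n_pairs,
                    settings = list(correlator = "multiple_tau", m = m,
                                    base_bin_s = base_bin_s, mode = mode,
                                    channels = c(i, j)))
}

#' Cross-correlation between the two detection channels
#'
#' Eq-2 cross-correlation (`i != j`) of a two-channel photon stream via the
#' multiple-tau correlator, mirroring the beam-splitter arrangement used to
#' avoid detector dead time; single-channel artifacts at antibunching lags
#' are suppressed by construction.
#'
#' @inheritParams multiple_tau_correlation
#' @param stream a two-channel [photon_stream()].
#' @return a raw-convention [correlation_curve()].
#' @export
cross_correlate_channels <- function(stream, m = 16L, base_bin_s = NULL,
                                     max_lag_s = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  for (ch in 1:2) {
    if (sum(stream$channel == ch) == 0L) {
      stop("channel ", ch, " is empty: cross-correlation undefined")
    }
  }
  multiple_tau_correlation(stream, i = 1L, j = 2L, m = m,
                           base_bin_s = base_bin_s, max_lag_s = max_lag_s)
}

#' Segment-based correlation uncertainties
#'
#' Splits the measurement into `n_segments` equal-length segments, computes
#' the correlation of each, and reports the per-lag mean as the value and
#' the standard error of the mean over segments as the uncertainty.
#'
#' @inheritParams multiple_tau_correlation
#' @param x a [photon_stream()] or sampled numeric series.
#' @param n_segments number of equal segments (default 10).
#' @param mode `"auto"` or `"cross"` (photon streams only; `"cross"` uses
#'   channels 1 and 2).
#' @param normalization photon streams only: `"shared"` (default)
#'   normalizes every segment by the full-measurement mean rates,
#'   `"segment"` by each segment's own overlapping-window means.
#' @return a raw-convention [correlation_curve()] with `sigma`.
#' @export
segment_errors <- function(x, n_segments = 10L, m = 16L, base_bin_s = NULL,
                           max_lag_s = NULL, dt_s = NULL,
                           mode = c("auto", "cross"),
                           normalization = c("shared", "segment")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  if (n_segments < 2L) stop("n_segments must be >= 2")
  if (inherits(x, "photon_stream")) {
    seg_dur <- x$duration_s / n_segments
    if (is.null(max_lag_s)) max_lag_s <- x$duration_s / 8
    if (max_lag_s > seg_dur / 4) {
      warning("segments shorter than 4x the maximum lag; ",
              "dropping the deepest correlator levels (max lag -> ",
              signif(seg_dur / 4, 3), " s)")
      max_lag_s <- seg_dur / 4
    }
    if (is.null(base_bin_s)) {
      tick_s <- x$tick_ps * .ps
      k <- max(0, ceiling(log2(seg_dur / tick_s / 2^22)))
      base_bin_s <- tick_s * 2^k
    }
    mu <- if (normalization == "shared") {
      ni <- sum(x$channel == 1L)
      nj <- if (mode == "cross") sum(x$channel == 2L) else ni
      c(ni, nj) * base_bin_s / x$duration_s  # expected counts per bin
    }
    curves <- lapply(seq_len(n_segments) - 1L, function(s) {
      t0 <- s * seg_dur
      ci <- bin_photons(x, 1L, base_bin_s, t0_s = t0, duration_s = seg_dur)
      cj <- if (mode == "cross") {
        bin_photons(x, 2L, base_bin_s, t0_s = t0, duration_s = seg_dur)
      } else ci
      if (is.null(mu)) mt_engine(ci, cj, base_bin_s, m, max_lag_s)
      else mt_engine(ci, cj, base_bin_s, m, max_lag_s,
                     mu_i = mu[1L], mu_j = mu[2L])
    })
  } else {
    if (is.null(dt_s)) stop("dt_s required for sampled signals")
    n <- length(x)
    seg_len <- floor(n / n_segments)
    seg_dur <- seg_len * dt_s
    if (is.null(max_lag_s)) max_lag_s <- n * dt_s / 8
    if (max_lag_s > seg_dur / 4) {
      warning("segments shorter than 4x the maximum lag; ",
              "dropping the deepest correlator levels (max lag -> ",
              signif(seg_dur / 4, 3), " s)")
      max_lag_s <- seg_dur / 4
    }
    curves <- lapply(seq_len(n_segments) - 1L, function(s) {
      seg <- as.numeric(x[seq.int(s * seg_len + 1L, (s + 1L) * seg_len)])
      mt_engine(seg, seg, dt_s, m, max_lag_s)
    })
    base_bin_s <- dt_s
  }
  # common lag grid: all segments share settings, so grids are identical
  lag_s <- curves[[1L]]$lag_s
  vmat <- vapply(curves, function(cu) {
    stopifnot(length(cu$value) == length(lag_s))
    cu$value
  }, numeric(length(lag_s)))
  vmat <- matrix(vmat, nrow = length(lag_s))
  value <- rowMeans(vmat)
  sigma <- apply(vmat, 1L, sd) / sqrt(n_segments)
  correlation_curve(lag_s, value, sigma = sigma, convention = "raw",
                    n_pairs = Reduce(`+`, lapply(curves, `[[`, "n_pairs")),
                    settings = list(correlator = "multiple_tau", m = m,
                                    base_bin_s = base_bin_s,
                                    n_segments = n_segments, mode = mode))
}

#' Write / read a correlation curve as 3-column delimited text
#'
#' Format: `lag_s<TAB>G<TAB>sigma` with `#` comment headers recording the
#' convention and correlator settings.
#'
#' @param curve a [correlation_curve()].
#' @param path file path.
#' @export
write_correlation <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  st <- curve$settings
  writeLines(c(sprintf("# petfcs correlation_curve convention=%s",
                       curve$convention),
               sprintf("# settings: %s",
                       if (is.null(st)) "none" else
                         paste(names(st), vapply(st, function(v)
                           paste(format(v), collapse = ","), ""),
                           sep = "=", collapse = " "))), con)
  df <- as.data.frame(curve)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_correlation
#' @return for `read_correlation`, the reconstructed [correlation_curve()].
#' @export
read_correlation <- function(path) {
  hdr <- readLines(path, n = 1L)
  convention <- sub(".*convention=(\\S+).*", "\\1", hdr)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  sigma <- if (all(is.na(df$sigma))) NULL else df$sigma
  correlation_curve(df$lag_s, df$G, sigma = sigma, convention = convention)
}
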