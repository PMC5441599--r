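test_that("direct correlator evaluates the definition exactly", {
  # constant signal: G = 1 at every lag
  cc <- direct_correlation(rep(3, 100), c(1, 5, 20), 1e-9)
  expect_equal(cc$value, rep(1, 3), tolerance = 1e-14)
  # alternating series: hand-evaluated time average
  x <- rep(c(1, 0), 500)
  cc <- direct_correlation(x, c(1, 2), 1e-9)
  expect_equal(cc$value[1], 0)
  expect_equal(cc$value[2], 2, tolerance = 1e-3)
  # errors
  expect_error(direct_correlation(rep(0, 50), 1, 1e-9), "zero-mean")
  expect_error(direct_correlation(x, 1000, 1e-9), "exceed")
})

test_that("long telegraph signals follow the analytic two-state correlation", {
  tp <- telegraph_params(5, 5, dt_ns = 2, n_steps = 1e6, seed = 31)
  s <- simulate_telegraph(tp)
  lags <- unique(round(10^seq(0.3, 3, length.out = 12)))
  cc <- direct_correlation(s$values, lags, s$dt_s)
  th <- telegraph_g(cc$lag_s, 5, 5)
  expect_lt(max(abs(cc$value - th)), 0.06)
})

test_that("autocorrelation is invariant under time reversal", {
  tp <- telegraph_params(4, 7, dt_ns = 5, n_steps = 5e4, seed = 32)
  s <- simulate_telegraph(tp)
  lags <- c(1, 3, 10, 40, 150)
  fw <- direct_correlation(s$values, lags, s$dt_s)
  bw <- direct_correlation(rev(s$values), lags, s$dt_s)
  # symmetric normalization makes this an exact identity
  expect_equal(fw$value, bw$value, tolerance = 1e-13)
})

test_that("multiple-tau equals the direct correlator at level-0 lags", {
  set.seed(33)
  x <- rpois(2e4, 3)
  mt <- multiple_tau_correlation(x, dt_s = 1e-6, m = 16,
                                 max_lag_s = 16e-6)
  dl <- direct_correlation(x, 1:16, 1e-6)
  expect_equal(mt$lag_s, dl$lag_s)
  expect_equal(mt$value, dl$value, tolerance = 1e-13)
})

test_that("multiple-tau agrees with the direct correlator on telegraph fixtures", {
  tp <- telegraph_params(5, 5, dt_ns = 1, n_steps = 1e6, seed = 34)
  s <- simulate_telegraph(tp)
  mt <- multiple_tau_correlation(s$values, dt_s = s$dt_s,
                                 max_lag_s = 2e-6)
  dl <- direct_correlation(s$values, round(mt$lag_s / s$dt_s), s$dt_s)
  expect_equal(dl$lag_s, mt$lag_s)
  expect_lt(max(abs(mt$value - dl$value) / dl$value), 0.02)
})

test_that("photon-mode multiple-tau overlays the binned-intensity correlation", {
  pp <- photon_sim_params(N = 1, D_um2_s = 0, brightness_cps = 1e6,
                          duration_s = 0.05, split = FALSE,
                          quench = list(k_form = 2, k_diss = 2),
                          positions_nm = matrix(0, 1, 3), seed = 35)
  st <- simulate_photons(pp)
  bin <- 64e-9
  m <- 16L
  mt <- multiple_tau_correlation(st, base_bin_s = bin, m = m,
                                 max_lag_s = 4e-6)
  t_s <- st$tick * st$tick_ps * 1e-12
  counts <- tabulate(floor(t_s / bin) + 1,
                     nbins = ceiling(st$duration_s / bin))
  # multiple-tau correlates counts coarsened to each level's bin width;
  # the direct oracle on the identically coarsened series must agree at
  # that level's lags (differences are normalization convention only)
  level <- 0L
  cur <- counts
  width <- bin
  checked <- 0L
  while (TRUE) {
    kset <- if (level == 0L) 1:m else (m / 2 + 1):m
    idx <- match(round(kset * width / bin), round(mt$lag_s / bin))
    idx <- idx[!is.na(idx) & abs(mt$lag_s[idx] - kset * width) < 1e-12]
    if (length(idx) == 0L) break
    dl <- direct_correlation(cur, round(mt$lag_s[idx] / width), width)
    expect_lt(max(abs(mt$value[idx] - dl$value) / dl$value), 0.02)
    checked <- checked + length(idx)
    n2 <- floor(length(cur) / 2) * 2
    cur <- cur[seq(1, n2, 2)] + cur[seq(2, n2, 2)]
    width <- width * 2
    level <- level + 1L
  }
  expect_equal(checked, length(mt$lag_s))
})

test_that("uncorrelated photon streams give a flat correlation of 1", {
  pp <- photon_sim_params(N = 1, D_um2_s = 0, brightness_cps = 4e5,
                          duration_s = 0.1, split = TRUE,
                          positions_nm = matrix(0, 1, 3), seed = 36)
  st <- simulate_photons(pp)
  for (md in c("auto", "cross")) {
    cv <- segment_errors(st, n_segments = 10, base_bin_s = 1e-6,
                         max_lag_s = 1e-3, mode = md)
    expect_lt(max(abs(cv$value - 1) / pmax(cv$sigma, 1e-9)), 4)
  }
})

test_that("a 50:50 split preserves the normalized dynamic correlation", {
  base <- list(N = 1, D_um2_s = 0, brightness_cps = 2e6,
               duration_s = 0.04, quench = list(k_form = 5, k_diss = 5),
               positions_nm = matrix(0, 1, 3), seed = 37)
  st_split <- simulate_photons(do.call(photon_sim_params,
                                       c(base, split = TRUE)))
  st_one <- simulate_photons(do.call(photon_sim_params,
                                     c(base, split = FALSE)))
  fit_dyn <- function(cv) {
    dyn <- correlation_curve(cv$lag_s, cv$value - 1,
                             sigma = 1 / sqrt(cv$n_pairs),
                             convention = "excess", n_pairs = cv$n_pairs)
    fit_two_state(dyn, convention = "telegraph_oracle")
  }
  f_cross <- fit_dyn(cross_correlate_channels(st_split, base_bin_s = 16e-9,
                                              max_lag_s = 3e-6))
  f_auto <- fit_dyn(multiple_tau_correlation(st_one, base_bin_s = 16e-9,
                                             max_lag_s = 3e-6))
  expect_lt(abs(f_cross$a_r - f_auto$a_r), 0.1)
  expect_lt(abs(f_cross$tau_r_s - f_auto$tau_r_s) / f_auto$tau_r_s, 0.15)
  # i = j reduces to the autocorrelation
  mt_ii <- multiple_tau_correlation(st_split, i = 1, j = 1,
                                    base_bin_s = 16e-9, max_lag_s = 3e-6)
  mt_auto <- multiple_tau_correlation(st_split, i = 1,
                                      base_bin_s = 16e-9, max_lag_s = 3e-6)
  expect_identical(mt_ii$value, mt_auto$value)
  expect_error(multiple_tau_correlation(st_one, m = 7), "even")
})

test_that("segment errors vanish for identical segments", {
  seg <- rep(c(1, 1, 0, 2, 0, 1, 3, 0, 1, 1), 30)
  x <- rep(seg, 10)
  cv <- segment_errors(x, n_segments = 10, dt_s = 1e-6,
                       max_lag_s = 20e-6)
  expect_equal(max(cv$sigma), 0, tolerance = 1e-14)
})

test_that("SEM shrinks as 1/sqrt(n) with more equal-length segments", {
  # fixed segment length; vary how many segments enter the estimate
  tp <- telegraph_params(5, 5, dt_ns = 20, n_steps = 4e5, seed = 38)
  s <- simulate_telegraph(tp)
  seg_len <- 2e4
  sem_for <- function(n_seg) {
    cv <- segment_errors(s$values[seq_len(seg_len * n_seg)],
                         n_segments = n_seg, dt_s = s$dt_s,
                         max_lag_s = 30 * s$dt_s)
    mean(cv$sigma)
  }
  ratio <- sem_for(5) / sem_for(20)
  expect_gt(ratio, 1.2)   # expected 2 = sqrt(20/5); the 5-segment SEM
  expect_lt(ratio, 3.2)   # estimate itself has few degrees of freedom
})

test_that("two-segment SEM reflects the half-difference of the halves", {
  s1 <- simulate_telegraph(telegraph_params(8, 2, dt_ns = 20,
                                            n_steps = 5e4, seed = 39))
  s2 <- simulate_telegraph(telegraph_params(2, 8, dt_ns = 20,
                                            n_steps = 5e4, seed = 40))
  x <- c(s1$values, s2$values)
  cv <- segment_errors(x, n_segments = 2, dt_s = s1$dt_s,
                       max_lag_s = 20 * s1$dt_s)
  c1 <- multiple_tau_correlation(s1$values, dt_s = s1$dt_s,
                                 max_lag_s = 20 * s1$dt_s)
  c2 <- multiple_tau_correlation(s2$values, dt_s = s2$dt_s,
                                 max_lag_s = 20 * s2$dt_s)
  expect_equal(cv$value, (c1$value + c2$value) / 2, tolerance = 1e-12)
  expect_equal(cv$sigma, abs(c1$value - c2$value) / 2, tolerance = 1e-12)
})

test_that("raw curves of stationary inputs converge to 1 at large lags", {
  tp <- telegraph_params(5, 5, dt_ns = 10, n_steps = 5e5, seed = 41)
  s <- simulate_telegraph(tp)
  cv <- segment_errors(s$values, n_segments = 10, dt_s = s$dt_s,
                       max_lag_s = 100e-6)
  tail_lags <- cv$lag_s > 10e-6  # >> tau_r = 100 ns
  z <- abs(cv$value[tail_lags] - 1) / pmax(cv$sigma[tail_lags], 1e-9)
  expect_lt(stats::quantile(z, 0.9), 3)
})

test_that("degenerate inputs are refused", {
  st <- photon_stream(numeric(0), integer(0), 16, 1)
  expect_error(multiple_tau_correlation(st), "empty")
  st1 <- photon_stream(5, 1L, 16, 1)
  expect_error(multiple_tau_correlation(st1), "single photon")
  expect_error(segment_errors(1:100, n_segments = 1, dt_s = 1e-6), ">= 2")
})
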