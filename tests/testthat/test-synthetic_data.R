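test_that("telegraph simulator reproduces the stationary bright fraction", {
  # SE of the mean of a correlated binary series: the effective number of
  # independent samples is about duration / (2 tau_r)
  cases <- list(c(5, 5, 0.5), c(7.4, 5.0, 5.0 / 12.4))
  for (cs in cases) {
    tp <- telegraph_params(cs[1], cs[2], dt_ns = 10, n_steps = 4e5,
                           seed = 11)
    s <- simulate_telegraph(tp)
    tau_r <- 1 / (cs[1] + cs[2]) * 1e-6
    n_eff <- duration_s(s) / (2 * tau_r)
    se <- sqrt(cs[3] * (1 - cs[3]) / n_eff)
    expect_lt(abs(mean(s$values) - cs[3]), 3 * se)
  }
})

test_that("telegraph dwell times are exponential in each state", {
  tp <- telegraph_params(5, 3, dt_ns = 10, n_steps = 1e6, seed = 2)
  s <- simulate_telegraph(tp)
  jumps <- s$truth$jumps_s
  dwell <- diff(jumps)
  # states alternate between jumps; the state during interval i is
  # determined by the initial state and i
  first_state_after <- 1L - s$truth$state0
  states <- (first_state_after + seq_along(dwell) - 1L) %% 2L
  d_bright <- dwell[states == 1L]  # terminated by rate k_form
  d_dark <- dwell[states == 0L]
  expect_gt(length(d_bright), 500)
  ks1 <- suppressWarnings(stats::ks.test(d_bright, "pexp", 5 / 1e-6))
  ks0 <- suppressWarnings(stats::ks.test(d_dark, "pexp", 3 / 1e-6))
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks0$p.value, 0.01)
})

test_that("simulators are reproducible bit-for-bit for a fixed seed", {
  tp <- telegraph_params(5, 5, dt_ns = 30, n_steps = 1e4, seed = 9)
  expect_identical(simulate_telegraph(tp)$values,
                   simulate_telegraph(tp)$values)
  tw <- function() simulate_two_well_distance(1, 3, 2, noise_sd_nm = 0.05,
                                              n_steps = 5e3, seed = 4)
  expect_identical(tw()$distance_nm, tw()$distance_nm)
  es <- ensemble_spec(make_centers(2), c(0.5, 0.5), 0.02, n_frames = 50,
                      seed = 5)
  expect_identical(simulate_ensemble(es)$frames, simulate_ensemble(es)$frames)
  pp <- photon_sim_params(N = 0.5, D_um2_s = 300, brightness_cps = 3e5,
                          duration_s = 0.01, seed = 6)
  s1 <- simulate_photons(pp); s2 <- simulate_photons(pp)
  expect_identical(s1$tick, s2$tick)
  expect_identical(s1$channel, s2$channel)
})

test_that("sampled telegraph autocorrelation matches the analytic form", {
  # k_form = k_diss = 5 /us: amplitude 1, relaxation 100 ns
  tp <- telegraph_params(5, 5, dt_ns = 1, n_steps = 2e6, seed = 21)
  s <- simulate_telegraph(tp)
  qa <- quench_autocorrelation(s, convention = "telegraph_oracle")
  expect_lt(abs(qa$fit$a_r - 1), 0.15)
  expect_lt(abs(qa$fit$tau_r_s - 100e-9) / 100e-9, 0.10)
  # curve itself overlays the analytic correlation
  th <- telegraph_g(qa$curve$lag_s, 5, 5) - 1
  expect_lt(max(abs(qa$curve$value - th)), 0.08)
})

test_that("two-well distance series has exact regime ground truth", {
  tw <- simulate_two_well_distance(1.0, 3.0, 2, noise_sd_nm = 0,
                                   dt_ns = 30, n_steps = 1e5, seed = 3)
  st <- classify_distance_series(tw$distance_nm, tw$dt_s)
  ct <- count_transitions(st)
  # noiseless: observed regime transitions equal grid-sampled hidden ones
  expect_identical(ct$N_T, tw$truth$n_hidden_sampled)
  # hidden jump count recovered within Poisson error of 2 r T
  expected <- 2 * 2 * duration_s(tw$hidden) / 1e-6 / 2  # r*T per direction x2
  expect_lt(abs(tw$truth$n_hidden_jumps - expected),
            4 * sqrt(expected))
  # zero hop rate: zero transitions
  tw0 <- simulate_two_well_distance(1.0, 3.0, 0, noise_sd_nm = 0,
                                    n_steps = 1e3, seed = 1)
  expect_identical(tw0$truth$n_hidden_jumps, 0L)
  st0 <- classify_distance_series(tw0$distance_nm, tw0$dt_s)
  expect_identical(count_transitions(st0)$N_T, 0L)
  # wells inside the intermediate band warn but do not error
  expect_warning(simulate_two_well_distance(1.25, 3, 1, noise_sd_nm = 0.05,
                                            n_steps = 100, seed = 1),
                 "intermediate")
})

test_that("planted ensembles carry their cluster structure", {
  centers <- make_centers(3, n_atoms = 12, spread = 1.0)
  es <- ensemble_spec(centers, weights = c(0.6, 0.3, 0.1),
                      within_cluster_sd_nm = 0.02, n_frames = 400,
                      seed = 8)
  en <- simulate_ensemble(es)
  sel <- seq_len(12)
  cl <- single_linkage_cluster(en, selection = sel, cutoff_nm = 0.25)
  expect_equal(cl$n_clusters, 3)
  # populations match planted weights within multinomial error (4 sigma)
  pop <- sort(cl$populations_pct, decreasing = TRUE) / 100
  for (i in 1:3) {
    w <- sort(es$weights, decreasing = TRUE)[i]
    expect_lt(abs(pop[i] - w), 4 * sqrt(w * (1 - w) / 400))
  }
  # single center: one cluster holding every frame
  es1 <- ensemble_spec(centers[1], within_cluster_sd_nm = 0.02,
                       n_frames = 100, seed = 9)
  cl1 <- single_linkage_cluster(simulate_ensemble(es1), selection = sel,
                                cutoff_nm = 0.25)
  expect_equal(cl1$n_clusters, 1)
  expect_equal(cl1$populations_pct, 100)
})

test_that("noise-free frames superpose exactly onto their planted centers", {
  centers <- make_centers(2, n_atoms = 10, spread = 1.2, seed = 13)
  es <- ensemble_spec(centers, weights = c(0.5, 0.5),
                      within_cluster_sd_nm = 0, n_frames = 30, seed = 14)
  en <- simulate_ensemble(es)
  a <- en$truth$assignment
  d_centers <- kabsch_rmsd_r(centers[[1]], centers[[2]])
  i1 <- which(a == 1L)[1L]; i2 <- which(a == 2L)[1L]
  # same center: rigid transform only, rmsd 0
  expect_lt(rmsd(en$frames[i1, , ], en$frames[which(a == 1L)[2L], , ]),
            1e-8)
  # different centers: pairwise rmsd equals the center-center rmsd
  expect_equal(rmsd(en$frames[i1, , ], en$frames[i2, , ]), d_centers,
               tolerance = 1e-6)
})

test_that("ensemble spec validates its invariants", {
  expect_error(ensemble_spec(list()), "non-empty")
  expect_error(ensemble_spec(make_centers(2), weights = c(0.7, 0.2)),
               "sum to 1")
})

test_that("an immobile emitter at the focus produces homogeneous Poisson photons", {
  pp <- photon_sim_params(N = 1, D_um2_s = 0, brightness_cps = 2e5,
                          duration_s = 0.1, split = FALSE,
                          positions_nm = matrix(0, 1, 3), seed = 10)
  st <- simulate_photons(pp)
  n <- length(st$tick)
  expect_lt(abs(n - 2e4), 4 * sqrt(2e4))
  # Poisson dispersion on binned counts
  t_s <- st$tick * st$tick_ps * 1e-12
  counts <- tabulate(floor(t_s / 1e-4) + 1, nbins = 1000)
  disp <- var(counts) / mean(counts)
  expect_lt(abs(disp - 1), 4 * sqrt(2 / 1000))
  # correlation flat at 1
  cv <- segment_errors(st, n_segments = 10, base_bin_s = 1e-6,
                       max_lag_s = 1e-3)
  expect_lt(max(abs(cv$value - 1) / pmax(cv$sigma, 1e-6)), 4)
})

test_that("photon stream recovers a planted 10 us diffusion time", {
  w <- 195
  D <- (w * 1e-3)^2 / (4 * 10e-6)  # tau_D = 10 us
  pp <- photon_sim_params(N = 1, w_nm = w, p = 5, D_um2_s = D,
                          brightness_cps = 1.5e6, duration_s = 0.05,
                          seed = 15)
  st <- simulate_photons(pp)
  cv <- segment_errors(st, n_segments = 10, base_bin_s = 2e-7,
                       max_lag_s = 1e-4, mode = "cross")
  f <- fit_fcs(cv, n_dyn = 0, triplet = FALSE, fixed = c(p = 5),
               start = list(tau_D_s = 3e-5))
  expect_true(f$converged)
  expect_lt(abs(f$estimate[["tau_D_s"]] - 1e-5) / 1e-5, 0.15)
})

test_that("quenching telegraph on an immobile emitter shows in the correlation", {
  pp <- photon_sim_params(N = 1, D_um2_s = 0, brightness_cps = 2e6,
                          duration_s = 0.04, split = FALSE,
                          quench = list(k_form = 5, k_diss = 5),
                          positions_nm = matrix(0, 1, 3), seed = 16)
  st <- simulate_photons(pp)
  cv <- multiple_tau_correlation(st, base_bin_s = 16e-9, max_lag_s = 3e-6)
  dyn <- correlation_curve(cv$lag_s, cv$value - 1,
                           sigma = 1 / sqrt(cv$n_pairs),
                           convention = "excess", n_pairs = cv$n_pairs)
  f <- fit_two_state(dyn, convention = "telegraph_oracle")
  expect_lt(abs(f$a_r - 1), 0.15)
  expect_lt(abs(f$tau_r_s - 100e-9) / 100e-9, 0.15)
  expect_lt(abs(f$rates$k_on_per_us - 5), 1)
})

test_that("the Brownian step resolution guard refuses coarse steps", {
  expect_error(simulate_photons(photon_sim_params(
    D_um2_s = 190, duration_s = 0.001, dt_sim_s = 1e-4, seed = 1)),
    "resolution guard")
})
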