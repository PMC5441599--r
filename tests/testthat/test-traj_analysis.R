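test_that("superposed RMSD solves the Kabsch problem", {
  set.seed(51)
  a <- matrix(rnorm(36), 12)
  expect_equal(rmsd(a, a), 0, tolerance = 1e-12)
  # rigid rotation + translation is removed by superposition
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(rmsd(a, a %*% t(R) + 2), 1e-7)
  # 3-atom toy with printed coordinates: Kabsch oracle + rotation grid
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.5, 0))
  B <- rbind(c(0.1, 0, 0.2), c(1.2, 0.1, 0), c(-0.1, 1.3, 0.1))
  r_impl <- rmsd(A, B)
  expect_equal(r_impl, kabsch_rmsd_r(A, B), tolerance = 1e-10)
  r_grid <- grid_rmsd_r(A, B, step_deg = 5)
  expect_gte(r_grid, r_impl - 1e-10)       # grid cannot beat the optimum
  expect_lt(r_grid - r_impl, 0.08 * r_impl + 0.02)
  expect_error(rmsd(a, a[1:5, ]), "matched")
})

test_that("superposed RMSD behaves as a pseudo-metric", {
  set.seed(52)
  frames <- lapply(1:8, function(i) matrix(rnorm(30, sd = 0.8), 10))
  D <- outer(1:8, 1:8, Vectorize(function(i, j) rmsd(frames[[i]],
                                                     frames[[j]])))
  expect_equal(D, t(D), tolerance = 1e-10)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-10)
  }
})

test_that("single linkage equals brute-force connected components", {
  centers <- make_centers(3, n_atoms = 10, spread = 1.0, seed = 53)
  es <- ensemble_spec(centers, weights = c(0.5, 0.3, 0.2),
                      within_cluster_sd_nm = 0.03, n_frames = 150,
                      seed = 54)
  en <- simulate_ensemble(es)
  sel <- seq_len(10)
  cl <- single_linkage_cluster(en, selection = sel, cutoff_nm = 0.25)
  D <- pairwise_rmsd(en, selection = sel)
  oracle <- components_bfs(D, 0.25)
  expect_true(same_partition(cl$cluster, oracle))
  # populations sorted descending, summing to 100
  expect_equal(sum(cl$populations_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(cl$populations_pct) <= 1e-12))
  # medoid minimizes the summed within-cluster RMSD
  m1 <- cl$medoid_frame[1L]
  members <- which(cl$cluster == 1L)
  sums <- rowSums(D[members, members, drop = FALSE])
  expect_equal(sum(D[m1, members]), min(sums), tolerance = 1e-10)
})

test_that("single-linkage chaining joins stepping-stone frames", {
  # frames 0.2 nm apart pairwise along a path, > 0.4 nm end to end
  base <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2, 1, 1, 0),
                 5, byrow = TRUE)
  shift <- matrix(0, 5, 3); shift[5, 1] <- sqrt(5 * 0.2^2)
  frames <- array(0, dim = c(4, 5, 3))
  for (f in 1:4) frames[f, , ] <- base + (f - 1) * shift
  atoms <- data.frame(residue = 1:5, resname = "ALA", atom = "CA",
                      element = "C")
  en <- trajectory_ensemble(atoms, base, frames, 1)
  D <- pairwise_rmsd(en, selection = 1:5)
  expect_lt(max(diag(D[-4, -1])), 0.25)  # successive frames linked
  expect_gt(D[1, 4], 0.4)                # ends far apart
  cl <- single_linkage_cluster(en, selection = 1:5, cutoff_nm = 0.25)
  expect_equal(cl$n_clusters, 1)
  # cutoff above the ensemble diameter also gives one cluster
  cl2 <- single_linkage_cluster(en, selection = 1:5,
                                cutoff_nm = max(D) * 1.1)
  expect_equal(cl2$n_clusters, 1)
})

test_that("clustering is invariant to frame order and to the pruned route", {
  centers <- make_centers(3, n_atoms = 10, spread = 1.0, seed = 55)
  es <- ensemble_spec(centers, weights = c(0.5, 0.3, 0.2),
                      within_cluster_sd_nm = 0.03, n_frames = 200,
                      seed = 56)
  en <- simulate_ensemble(es)
  sel <- seq_len(10)
  cl <- single_linkage_cluster(en, selection = sel, cutoff_nm = 0.25)
  # permuted frame order
  set.seed(57)
  perm <- sample(n_frames(en))
  en_p <- trajectory_ensemble(en$atoms, en$ref,
                              en$frames[perm, , , drop = FALSE],
                              en$dt_frame_ns)
  cl_p <- single_linkage_cluster(en_p, selection = sel, cutoff_nm = 0.25)
  expect_identical(cl_p$cluster, cl$cluster[perm])
  expect_equal(cl_p$populations_pct, cl$populations_pct)
  # pivot-pruned route gives the identical partition
  cl_pr <- single_linkage_cluster(en, selection = sel, cutoff_nm = 0.25,
                                  exact_max = 10L)
  expect_identical(cl_pr$cluster, cl$cluster)
  expect_error(single_linkage_cluster(en, selection = sel,
                                      max_frames = 100L), "desk-scale")
})

test_that("minimum RMSD to reference structures behaves as constructed", {
  centers <- make_centers(2, n_atoms = 10, spread = 1.0, seed = 58)
  sd_n <- 0.02
  es <- ensemble_spec(centers[1], within_cluster_sd_nm = sd_n,
                      n_frames = 200, seed = 59)
  en <- simulate_ensemble(es)
  sel <- seq_len(10)
  # a member frame as target: exact zero
  tgt <- en$frames[7, , ]
  mr <- min_rmsd_to_reference(en, tgt, selection = sel)
  expect_lt(mr$min_rmsd_nm, 1e-6)
  expect_equal(mr$argmin_frame, 7)
  # own center: noise floor, chi-distributed around sd * sqrt((3n-7)/n)
  mr0 <- min_rmsd_to_reference(en, centers[[1]], selection = sel)
  floor_pred <- sd_n * sqrt((3 * 10 - 7) / 10)
  expect_lt(mr0$min_rmsd_nm, 1.1 * floor_pred)
  expect_gt(mr0$min_rmsd_nm, 0.2 * floor_pred)
  # a second center a known (superposed) RMSD away from the planted one
  c2 <- centers[[1]]
  c2[1, ] <- c2[1, ] + c(sqrt(10 * 0.5^2), 0, 0)
  d_true <- kabsch_rmsd_r(centers[[1]], c2)
  mr2 <- min_rmsd_to_reference(en, list(centers[[1]], c2),
                               selection = sel)
  expect_equal(mr2$min_rmsd_nm[2], d_true, tolerance = 0.1)
})

test_that("end-to-end distances classify into strict regimes", {
  tw <- simulate_two_well_distance(1.0, 3.0, 2, noise_sd_nm = 0,
                                   n_steps = 2e4, seed = 60)
  st <- classify_distance_series(tw$distance_nm, tw$dt_s)
  expect_identical(st$values, tw$hidden$values)
  # boundary values are intermediate (strict inequalities)
  stb <- classify_distance_series(c(1.3, 2.5, 1.2999, 2.5001), 1e-9)
  expect_identical(stb$values,
                   c("intermediate", "intermediate", "close", "open"))
})

test_that("end-to-end series from an ensemble uses the terminal C-beta atoms", {
  q <- telegraph_params(5, 5, dt_ns = 30, n_steps = 400, seed = 61)
  en <- simulate_peptide_trajectory(q, noise_sd_nm = 0)
  ee <- end_to_end_series(en)
  expect_equal(ee$distance_nm, en$truth$two_well$distance_nm,
               tolerance = 1e-9)
  oracle <- classify_distance_series(en$truth$two_well$distance_nm,
                                     ee$states$dt_s)
  expect_identical(ee$states$values, oracle$values)
  # a residue without C-beta is reported by name
  en2 <- en
  en2$atoms$atom[en2$atoms$residue == 14] <- "CG"
  expect_error(end_to_end_series(en2), "residue 14")
})

test_that("transition counting uses last-assigned-regime semantics", {
  mk <- function(v, dt) state_sequence(v, dt, "ternary")
  ct <- count_transitions(mk(c("open", "close", "open", "close"), 0.25e-6))
  expect_identical(ct$N_T, 3L)
  expect_equal(ct$rate_per_us, 3)
  # intermediate excursion returning to the same regime does not count
  expect_identical(count_transitions(
    mk(c("open", "intermediate", "open"), 1e-6))$N_T, 0L)
  # intermediate frames keep the previous regime across a real switch
  expect_identical(count_transitions(
    mk(c("open", "intermediate", "close"), 1e-6))$N_T, 1L)
  # leading intermediates are unlabeled and uncounted
  expect_identical(count_transitions(
    mk(c("intermediate", "open", "close"), 1e-6))$N_T, 1L)
  # never assigned: N_T = 0 with a warning
  expect_warning(ct0 <- count_transitions(
    mk(rep("intermediate", 5), 1e-6)), "ever assigned")
  expect_identical(ct0$N_T, 0L)
  # invariant under time reversal
  set.seed(62)
  v <- sample(c("open", "intermediate", "close"), 500, replace = TRUE)
  expect_identical(count_transitions(mk(v, 1e-6))$N_T,
                   count_transitions(mk(rev(v), 1e-6))$N_T)
})

test_that("quenching classification applies the strict ring-center criterion", {
  # two 9-atom rings whose centers sit at controlled distances
  ring <- cbind(0.14 * cos(2 * pi * (0:8) / 9),
                0.14 * sin(2 * pi * (0:8) / 9), 0)
  trp_names <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                 "CH2")
  atoms <- rbind(
    data.frame(residue = 0L, resname = "DYE", atom = sprintf("C%d", 1:9),
               element = "C"),
    data.frame(residue = 15L, resname = "TRP", atom = trp_names,
               element = "C"))
  seps <- c(0.50, 0.56, 0.55)
  frames <- array(0, dim = c(3, 18, 3))
  for (f in 1:3) {
    frames[f, 1:9, ] <- ring
    frames[f, 10:18, ] <- sweep(ring, 2, c(seps[f], 0, 0), `+`)
  }
  en <- trajectory_ensemble(atoms, frames[1, , ], frames, 30)
  crit <- quench_criterion(group_A = list(residue = 0L,
                                          atoms = sprintf("C%d", 1:9)))
  qs <- quench_series(en, crit)
  expect_identical(qs$values, c(0L, 1L, 1L))  # dark / bright / bright at r*
  expect_equal(qs$truth$center_distance_nm, seps, tolerance = 1e-12)
  # unresolvable group names are listed
  bad <- quench_criterion(group_A = list(residue = 0L,
                                         atoms = c("C1", "CX9")))
  expect_error(quench_series(en, bad), "CX9")
})

test_that("quench autocorrelation recovers telegraph kinetics and amplitude", {
  # rates summing to 13.9 /us: relaxation 1/13.9 us = 72 ns
  tp <- telegraph_params(8.4, 5.5, dt_ns = 30, n_steps = 6e5, seed = 63)
  s <- simulate_telegraph(tp)
  qa <- quench_autocorrelation(s, convention = "telegraph_oracle")
  expect_lt(abs(qa$fit$tau_r_s - 71.9e-9) / 71.9e-9, 0.12)
  # amplitude matches (dark fraction)/(bright fraction) = k_form/k_diss
  expect_lt(abs(qa$fit$a_r - 8.4 / 5.5) / (8.4 / 5.5), 0.15)
  expect_error(quench_autocorrelation(
    state_sequence(rep(1L, 100), 1e-9, "binary")), "never changes")
})

test_that("discarding a planted equilibration period shortens the fitted relaxation", {
  # slow dynamics in the first 40% of the signal, fast afterwards
  s_slow <- simulate_telegraph(telegraph_params(1.2, 1.1, dt_ns = 30,
                                                n_steps = 4e5, seed = 64))
  s_fast <- simulate_telegraph(telegraph_params(8.4, 5.5, dt_ns = 30,
                                                n_steps = 6e5, seed = 65))
  s <- state_sequence(c(s_slow$values, s_fast$values), 30e-9, "binary")
  full <- quench_autocorrelation(s)
  post <- quench_autocorrelation(s, start_offset_s = 0.4 * duration_s(s))
  expect_gt(full$fit$tau_r_s, 1.5 * post$fit$tau_r_s)
  expect_lt(abs(post$fit$tau_r_s - 71.9e-9) / 71.9e-9, 0.15)
})
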