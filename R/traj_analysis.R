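#' RMSD after optimal rigid-body superposition
#'
#' Root-mean-square deviation of two coordinate sets after least-squares
#' superposition (Kabsch rotation + translation) of the compared selection.
#' Superposition is always applied; RMSD on superposed selections is a
#' pseudo-metric (symmetric, triangle inequality), which the pruned
#' neighbor search in [single_linkage_cluster()] relies on.
#'
#' @param frame_a,frame_b `n_atoms x 3` coordinate matrices (nm) with atoms
#'   aligned one-to-one.
#' @return RMSD in nm.
#' @export
rmsd <- function(frame_a, frame_b) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b) ||
      ncol(frame_a) != 3L || ncol(frame_b) != 3L ||
      nrow(frame_a) != nrow(frame_b)) {
    stop("selections must be matched n_atoms x 3 matrices")
  }
  rmsd_pair_cpp(coords_flat(frame_a), coords_flat(frame_b))
}

#' Pairwise superposed RMSD matrix of an ensemble
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param selection integer atom indices (default: all heavy atoms of
#'   residues 1-14).
#' @return symmetric `n_frames x n_frames` matrix, nm.
#' @export
pairwise_rmsd <- function(ensemble, selection = NULL) {
  if (is.null(selection)) {
    selection <- select_atoms(ensemble, residues = 1:14, heavy_only = TRUE)
  }
  rmsd_pairwise_cpp(frames_flat(ensemble, selection))
}

# Union-find with path compression.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

components_from_pairs <- function(n, ii, jj) {
  parent <- seq_len(n)
  for (k in seq_along(ii)) {
    ri <- uf_find(parent, ii[k])
    rj <- uf_find(parent, jj[k])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

#' Single-linkage conformational clustering
#'
#' Clusters trajectory frames as the connected components of the graph
#' with an edge wherever the pairwise superposed RMSD is strictly below
#' the cutoff (0.25 nm by default). Clusters are sorted and numbered by
#' their frequency of occurrence (cluster 1 is the most populated) and the
#' representative of each cluster is its medoid, the member frame with the
#' smallest summed RMSD to all other members.
#'
#' For up to `exact_max` frames the full pairwise RMSD matrix is computed.
#' Beyond that a pivot-based search is used: RMSDs to a small set of pivot
#' frames give the triangle-inequality lower bound
#' `max_p |d(i,p) - d(j,p)|`, and only pairs whose bound is below the
#' cutoff are evaluated exactly. Both routes give identical components.
#' The desk-scale default refuses more than 20000 frames.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param selection atom indices to cluster on (default: heavy atoms of
#'   residues 1-14).
#' @param cutoff_nm RMSD cutoff, nm (default 0.25).
#' @param exact_max largest frame count for the full-matrix route.
#' @param n_pivots number of pivot frames for the pruned route.
#' @param max_frames hard limit on frame count.
#' @return object of class `cluster_result`: list with `cluster` (per-frame
#'   1-based index, population-sorted), `populations_pct`, `medoid_frame`,
#'   `n_clusters`, `cutoff_nm`.
#' @export
single_linkage_cluster <- function(ensemble, selection = NULL,
                                   cutoff_nm = 0.25, exact_max = 3000L,
                                   n_pivots = 8L, max_frames = 20000L) {
  if (is.null(selection)) {
    selection <- select_atoms(ensemble, residues = 1:14, heavy_only = TRUE)
  }
  stop_if_not_scalar_pos(cutoff_nm, "cutoff_nm")
  X <- frames_flat(ensemble, selection)
  n <- nrow(X)
  if (n < 1L) stop("ensemble has no frames")
  if (n > max_frames) {
    stop("ensemble exceeds the desk-scale limit of ", max_frames,
         " frames; subsample or raise max_frames")
  }
  if (n <= exact_max) {
    D <- rmsd_pairwise_cpp(X)
    hits <- which(D < cutoff_nm & upper.tri(D), arr.ind = TRUE)
    comp <- components_from_pairs(n, hits[, 1L], hits[, 2L])
  } else {
    pivots <- unique(as.integer(round(seq(1L, n, length.out = n_pivots))))
    P <- rmsd_cross_cpp(X, X[pivots, , drop = FALSE])  # n x n_pivots
    ii <- integer(0); jj <- integer(0)
    block <- 512L
    for (b0 in seq(1L, n - 1L, by = block)) {
      b1 <- min(b0 + block - 1L, n - 1L)
      rows <- b0:b1
      lb <- matrix(0, length(rows), n)
      for (p in seq_along(pivots)) {
        lb <- pmax(lb, abs(outer(P[rows, p], P[, p], `-`)))
      }
      cand <- which(lb < cutoff_nm, arr.ind = TRUE)
      keep <- rows[cand[, 1L]] < cand[, 2L]
      ii <- c(ii, rows[cand[keep, 1L]])
      jj <- c(jj, cand[keep, 2L])
    }
    d <- rmsd_pairs_cpp(X, ii, jj)
    sel <- d < cutoff_nm
    comp <- components_from_pairs(n, ii[sel], jj[sel])
    D <- NULL
  }
  sizes <- tabulate(comp)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- match(seq_along(sizes), ord)
  cluster <- relabel[comp]
  sizes <- sizes[ord]
  k <- length(sizes)
  medoid <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(cluster == cl)
    if (length(members) == 1L) { medoid[cl] <- members; next }
    Dm <- if (!is.null(D)) D[members, members, drop = FALSE] else {
      rmsd_pairwise_cpp(X[members, , drop = FALSE])
    }
    medoid[cl] <- members[which.min(rowSums(Dm))]
  }
  structure(list(cluster = cluster,
                 populations_pct = 100 * sizes / n,
                 medoid_frame = medoid, n_clusters = k,
                 cutoff_nm = cutoff_nm, selection = selection),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters at %.3g nm cutoff\n",
              x$n_clusters, x$cutoff_nm))
  top <- head(seq_len(x$n_clusters), 10L)
  cat("  populations (%):",
      paste(sprintf("#%d %.1f", top, x$populations_pct[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Minimum RMSD of an ensemble to one or more reference structures
#'
#' Minimum over the frames of an ensemble of the superposed RMSD to each
#' target structure, used to ask whether one simulation ever approaches the
#' representative structures of another.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param targets a single `n_sel x 3` matrix, a list of such matrices, or
#'   a second ensemble (its frames become targets). Coordinates restricted
#'   to `selection` already, or full frames with `selection` applied.
#' @param selection atom indices (applied to `ensemble`, and to `targets`
#'   when these are full-size frames).
#' @return data frame with one row per target: `min_rmsd_nm`,
#'   `argmin_frame`.
#' @export
min_rmsd_to_reference <- function(ensemble, targets, selection = NULL) {
  if (is.null(selection)) {
    selection <- select_atoms(ensemble, residues = 1:14, heavy_only = TRUE)
  }
  X <- frames_flat(ensemble, selection)
  if (nrow(X) == 0L) stop("ensemble has no frames")
  as_target_row <- function(m) {
    if (nrow(m) == nrow(ensemble$atoms)) m <- m[selection, , drop = FALSE]
    if (nrow(m) != length(selection)) stop("target selection mismatch")
    coords_flat(m)
  }
  Y <- if (inherits(targets, "trajectory_ensemble")) {
    frames_flat(targets, selection)
  } else if (is.list(targets) && !is.matrix(targets)) {
    do.call(rbind, lapply(targets, as_target_row))
  } else {
    as_target_row(targets)
  }
  D <- rmsd_cross_cpp(X, Y)  # n_frames x n_targets
  data.frame(target = seq_len(ncol(D)),
             min_rmsd_nm = apply(D, 2L, min),
             argmin_frame = apply(D, 2L, which.min))
}

#' End-to-end distance regime thresholds
#'
#' @param d_close_nm upper bound of the "close" regime (strict, default
#'   1.3 nm).
#' @param d_open_nm lower bound of the "open" regime (strict, default
#'   2.5 nm).
#' @param residues the two residues whose C-beta atoms define the
#'   end-to-end distance (default 1 and 14).
#' @return object of class `regime_thresholds`.
#' @export
regime_thresholds <- function(d_close_nm = 1.3, d_open_nm = 2.5,
                              residues = c(1L, 14L)) {
  if (d_close_nm >= d_open_nm) stop("d_close_nm must be < d_open_nm")
  structure(list(d_close_nm = d_close_nm, d_open_nm = d_open_nm,
                 residues = residues),
            class = "regime_thresholds")
}

# Classify distances into regimes with strict inequalities.
classify_regime <- function(d_nm, thresholds) {
  ifelse(d_nm < thresholds$d_close_nm, "close",
         ifelse(d_nm > thresholds$d_open_nm, "open", "intermediate"))
}

#' End-to-end distance series and regime classification
#'
#' Per-frame Euclidean distance between the C-beta atoms of the two
#' terminal residues, classified into `close` (d < 1.3 nm), `open`
#' (d > 2.5 nm) or `intermediate` (boundaries are strict: a distance of
#' exactly 1.3 nm is intermediate).
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param thresholds a [regime_thresholds()].
#' @return list with `distance_nm` and `states` (ternary
#'   [state_sequence()]).
#' @export
end_to_end_series <- function(ensemble, thresholds = regime_thresholds()) {
  at <- ensemble$atoms
  idx <- vapply(thresholds$residues, function(r) {
    i <- which(at$residue == r & at$atom == "CB")
    if (length(i) != 1L) {
      stop("residue ", r, " (", paste(unique(at$resname[at$residue == r]),
                                      collapse = "/"),
           ") has no unique C-beta atom")
    }
    i
  }, integer(1))
  dxyz <- ensemble$frames[, idx[1L], ] - ensemble$frames[, idx[2L], ]
  d <- sqrt(rowSums(dxyz^2))
  dt_s <- ensemble$dt_frame_ns * .ns
  list(distance_nm = d,
       states = state_sequence(classify_regime(d, thresholds), dt_s,
                               "ternary"))
}

#' @rdname end_to_end_series
#' @param distance_nm a plain distance series (nm) to classify directly.
#' @param dt_s its sampling interval, seconds.
#' @export
classify_distance_series <- function(distance_nm, dt_s,
                                     thresholds = regime_thresholds()) {
  state_sequence(classify_regime(distance_nm, thresholds), dt_s, "ternary")
}

#' Count open/close regime transitions and the mean transition rate
#'
#' Counts regime switches with last-assigned-regime (hysteresis)
#' semantics: intermediate frames keep the previously assigned regime, so
#' an excursion into the intermediate band that returns to the same regime
#' does not count. A transition is counted at every switch of the assigned
#' regime, in both directions. The mean rate of opening and closing events
#' is `N_T` divided by the total time.
#'
#' @param states a ternary [state_sequence()].
#' @param total_time_s total time to divide by (default: the sampled
#'   duration of `states`).
#' @return list with `N_T`, `rate_per_us`, and `total_time_s`.
#' @examples
#' s <- state_sequence(c("open", "close", "open", "close"), 0.25e-6, "ternary")
#' count_transitions(s)  # N_T = 3 over 1 us -> 3 per us
#' @export
count_transitions <- function(states, total_time_s = NULL) {
  stopifnot(inherits(states, "state_sequence"), states$kind == "ternary")
  if (length(states$values) < 2L) stop("need at least 2 frames")
  if (is.null(total_time_s)) total_time_s <- duration_s(states)
  assigned <- states$values[states$values != "intermediate"]
  if (length(assigned) == 0L) {
    warning("no frame was ever assigned to the open or close regime")
    return(list(N_T = 0L, rate_per_us = 0,
                total_time_s = total_time_s))
  }
  n_t <- sum(assigned[-1L] != assigned[-length(assigned)])
  list(N_T = n_t, rate_per_us = n_t / (total_time_s / .us),
       total_time_s = total_time_s)
}

#' Quenching-contact criterion
#'
#' Defines the dark/fluorescent classification: a frame is dark when the
#' distance between the unweighted geometric centers of the fluorophore
#' ring system and the quencher ring system is strictly below the
#' quenching distance `r*` (0.55 nm by default).
#'
#' Groups are given as `list(residue = , atoms = )` (atom names within one
#' residue) or as plain integer atom indices. The Trp side-chain ring
#' system is the default quencher group; the fluorophore ring system has
#' no standard naming and must be supplied.
#'
#' @param group_A fluorophore ring-system group.
#' @param group_B quencher ring-system group; default: Trp ring atoms
#'   (`CG, CD1, CD2, NE1, CE2, CE3, CZ2, CZ3, CH2`) of residue 15.
#' @param r_star_nm quenching distance, nm.
#' @return object of class `quench_criterion`.
#' @export
quench_criterion <- function(group_A,
                             group_B = list(residue = 15L,
                                            atoms = trp_ring_atoms()),
                             r_star_nm = 0.55) {
  stop_if_not_scalar_pos(r_star_nm, "r_star_nm")
  structure(list(group_A = group_A, group_B = group_B,
                 r_star_nm = r_star_nm),
            class = "quench_criterion")
}

resolve_group <- function(ensemble, group, label) {
  at <- ensemble$atoms
  if (is.numeric(group)) {
    idx <- as.integer(group)
    if (any(idx < 1L | idx > nrow(at))) {
      stop("atom indices of ", label, " out of range")
    }
    return(idx)
  }
  idx <- which(at$residue == group$residue & at$atom %in% group$atoms)
  missing <- setdiff(group$atoms, at$atom[at$residue == group$residue])
  if (length(missing) > 0L) {
    stop("unresolvable atoms in ", label, " (residue ", group$residue,
         "): ", paste(missing, collapse = ", "))
  }
  idx
}

#' Classify trajectory frames into dark and fluorescent states
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param criterion a [quench_criterion()].
#' @return binary [state_sequence()] (1 = fluorescent, 0 = dark).
#' @export
quench_series <- function(ensemble, criterion) {
  stopifnot(inherits(criterion, "quench_criterion"))
  ia <- resolve_group(ensemble, criterion$group_A, "group_A")
  ib <- resolve_group(ensemble, criterion$group_B, "group_B")
  if (length(intersect(ia, ib)) > 0L) {
    stop("fluorophore and quencher groups must be disjoint")
  }
  center <- function(idx) {
    # mean coordinate over the group, per frame: n_frames x 3
    apply(ensemble$frames[, idx, , drop = FALSE], c(1L, 3L), mean)
  }
  dxyz <- center(ia) - center(ib)
  d <- sqrt(rowSums(dxyz^2))
  state_sequence(as.integer(!(d < criterion$r_star_nm)),
                 ensemble$dt_frame_ns * .ns, "binary",
                 truth = list(center_distance_nm = d))
}

#' Quenching autocorrelation of a binary state series and its two-state fit
#'
#' Direct normalized autocorrelation of the fluorescent (bright) signal on
#' a quasi-logarithmic lag subset, minus 1 (excess convention), fitted
#' with the single-exponential two-state model `a_r exp(-tau/tau_r)`.
#' Supports an analysis-window start offset to discard an initial
#' equilibration period, and restricts the fit to lags with at least
#' `min_pairs` contributing products (the estimate converges poorly at the
#' largest lags).
#'
#' @param states a binary [state_sequence()].
#' @param start_offset_s discard this initial stretch of signal before
#'   correlating (default 0).
#' @param max_lag_s largest lag (default 1/10 of the analyzed window).
#' @param n_per_decade lag density of the logarithmic grid.
#' @param min_pairs minimum number of contributing products per fitted
#'   lag.
#' @param fit if `FALSE`, return only the curve.
#' @param convention rate convention passed to [rates_from_dynamics()].
#' @return list with `curve` (excess [correlation_curve()]) and `fit` (a
#'   `dynamic_fit` from [fit_two_state()], with rates attached).
#' @export
quench_autocorrelation <- function(states, start_offset_s = 0,
                                   max_lag_s = NULL, n_per_decade = 16,
                                   min_pairs = 100, fit = TRUE,
                                   convention = c("as_printed",
                                                  "telegraph_oracle")) {
  stopifnot(inherits(states, "state_sequence"), states$kind == "binary")
  convention <- match.arg(convention)
  v <- states$values
  if (start_offset_s > 0) {
    drop <- floor(start_offset_s / states$dt_s)
    if (drop >= length(v)) stop("start offset removes the whole signal")
    v <- v[-seq_len(drop)]
  }
  if (all(v == 1L) || all(v == 0L)) {
    stop("signal never changes state: correlation amplitude undefined")
  }
  if (is.null(max_lag_s)) max_lag_s <- length(v) * states$dt_s / 10
  max_lag <- min(floor(max_lag_s / states$dt_s), length(v) - min_pairs)
  lags <- log_lags(max_lag, n_per_decade)
  curve <- direct_correlation(v, lags, states$dt_s)
  keep <- curve$n_pairs >= min_pairs
  # relative weights from the pair count: the sampling error of the
  # estimate scales as 1/sqrt(number of contributing products)
  curve <- correlation_curve(curve$lag_s[keep], curve$value[keep] - 1,
                             sigma = 1 / sqrt(curve$n_pairs[keep]),
                             convention = "excess",
                             n_pairs = curve$n_pairs[keep],
                             settings = list(correlator = "direct_log",
                                             start_offset_s = start_offset_s))
  out <- list(curve = curve)
  if (fit) out$fit <- fit_two_state(curve, convention = convention)
  out
}
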