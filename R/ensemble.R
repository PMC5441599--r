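#' Trajectory ensemble container
#'
#' A reference structure plus per-frame coordinates with atom metadata, the
#' input of all trajectory post-processing steps.
#'
#' @param atoms data frame with columns `residue` (1-based index),
#'   `resname`, `atom` (atom name), `element`.
#' @param ref reference coordinates, `n_atoms x 3` matrix, nm.
#' @param frames per-frame coordinates, array `n_frames x n_atoms x 3`, nm.
#' @param dt_frame_ns frame spacing, ns.
#' @param truth optional generator ground truth.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(atoms, ref, frames, dt_frame_ns,
                                truth = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("residue", "resname", "atom", "element") %in% names(atoms)))
  n_atoms <- nrow(atoms)
  if (!is.matrix(ref) || nrow(ref) != n_atoms || ncol(ref) != 3L) {
    stop("ref must be an n_atoms x 3 matrix")
  }
  if (length(dim(frames)) != 3L || dim(frames)[2] != n_atoms ||
      dim(frames)[3] != 3L) {
    stop("frames must be an n_frames x n_atoms x 3 array")
  }
  if (!all(is.finite(frames))) stop("coordinates must be finite")
  stop_if_not_scalar_pos(dt_frame_ns, "dt_frame_ns")
  structure(list(atoms = atoms, ref = ref, frames = frames,
                 dt_frame_ns = dt_frame_ns, truth = truth),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d frames x %d atoms (%d residues), dt = %g ns\n",
              dim(x$frames)[1], nrow(x$atoms),
              length(unique(x$atoms$residue)), x$dt_frame_ns))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x a [trajectory_ensemble()].
#' @export
n_frames <- function(x) dim(x$frames)[1]

#' Select atoms of an ensemble
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param residues residue indices to keep (default all).
#' @param atom_names atom names to keep (default all).
#' @param heavy_only if `TRUE`, drop hydrogens (element `"H"`).
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(ensemble, residues = NULL, atom_names = NULL,
                         heavy_only = FALSE) {
  at <- ensemble$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(residues)) keep <- keep & at$residue %in% residues
  if (!is.null(atom_names)) keep <- keep & at$atom %in% atom_names
  if (heavy_only) keep <- keep & at$element != "H"
  idx <- which(keep)
  if (length(idx) == 0L) stop("atom selection is empty")
  idx
}

# Flatten selected frame coordinates into the n_frames x (3 n_sel) layout
# expected by the compiled RMSD kernels (x1, y1, z1, x2, ...).
frames_flat <- function(ensemble, sel = NULL) {
  fr <- ensemble$frames
  if (!is.null(sel)) fr <- fr[, sel, , drop = FALSE]
  nf <- dim(fr)[1]; na <- dim(fr)[2]
  out <- matrix(0, nf, 3L * na)
  for (d in 1:3) out[, seq(d, 3L * na, by = 3L)] <- fr[, , d]
  out
}

coords_flat <- function(coords) {
  # single n_atoms x 3 matrix -> 1 x (3 n_atoms) row
  matrix(t(coords), nrow = 1L)
}

#' Specification of a planted-cluster conformational ensemble
#'
#' Frames are drawn by choosing a planted center structure according to
#' `weights`, adding isotropic Gaussian coordinate noise, and applying a
#' random rigid rotation and translation (so any clustering must
#' superpose).
#'
#' Separability: the pairwise superposed RMSD of two frames from the same
#' center concentrates around `sqrt(2) * within_cluster_sd_nm`, while
#' frames from different centers sit near the center-center RMSD. Planted
#' clusters are cleanly separable at a single-linkage cutoff `c` when
#' `3 * sqrt(2) * within_cluster_sd_nm < c` and all center-center RMSDs
#' exceed `2 c`.
#'
#' @param center_structures list of `n_atoms x 3` coordinate matrices (nm),
#'   one per planted cluster.
#' @param weights per-cluster probabilities (summing to 1).
#' @param within_cluster_sd_nm per-coordinate Gaussian noise, nm.
#' @param n_frames number of frames to draw.
#' @param dt_frame_ns frame spacing, ns.
#' @param seed integer seed.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(center_structures, weights = NULL,
                          within_cluster_sd_nm = 0.02, n_frames = 500,
                          dt_frame_ns = 30, seed = 1L) {
  if (!is.list(center_structures) || length(center_structures) == 0L) {
    stop("center_structures must be a non-empty list of coordinate matrices")
  }
  k <- length(center_structures)
  na <- nrow(center_structures[[1L]])
  for (cs in center_structures) {
    if (!is.matrix(cs) || ncol(cs) != 3L || nrow(cs) != na) {
      stop("all centers must be n_atoms x 3 matrices with matching n_atoms")
    }
  }
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative, one per center, and sum to 1")
  }
  if (within_cluster_sd_nm < 0) stop("within_cluster_sd_nm must be >= 0")
  structure(list(center_structures = center_structures, weights = weights,
                 within_cluster_sd_nm = within_cluster_sd_nm,
                 n_frames = as.integer(n_frames),
                 dt_frame_ns = dt_frame_ns, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det = +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Simulate a planted-cluster conformational ensemble
#'
#' @param spec an [ensemble_spec()].
#' @return a [trajectory_ensemble()] whose `truth$assignment` records the
#'   planted cluster of every frame. Atom metadata is generic (one CA-like
#'   pseudo-atom per residue).
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  k <- length(spec$center_structures)
  if (k >= 2L && length(spec$center_structures) < 2L) {
    stop("k_clusters >= 2 requires at least 2 centers")
  }
  set.seed(spec$seed)
  na <- nrow(spec$center_structures[[1L]])
  assignment <- sample.int(k, spec$n_frames, replace = TRUE,
                           prob = spec$weights)
  frames <- array(0, dim = c(spec$n_frames, na, 3L))
  for (f in seq_len(spec$n_frames)) {
    x <- spec$center_structures[[assignment[f]]]
    if (spec$within_cluster_sd_nm > 0) {
      x <- x + matrix(rnorm(3L * na, sd = spec$within_cluster_sd_nm), na)
    }
    x <- x %*% t(random_rotation())
    x <- sweep(x, 2L, rnorm(3L, sd = 2), `+`)  # random translation
    frames[f, , ] <- x
  }
  atoms <- data.frame(residue = seq_len(na),
                      resname = rep("ALA", na),
                      atom = rep("CA", na),
                      element = rep("C", na))
  trajectory_ensemble(atoms, spec$center_structures[[1L]], frames,
                      spec$dt_frame_ns,
                      truth = list(assignment = assignment,
                                   weights = spec$weights,
                                   within_cluster_sd_nm =
                                     spec$within_cluster_sd_nm))
}

# Planar ring of n_ring atoms with given radius (nm) centered at the
# origin in the xy plane.
ring_coords <- function(n_ring, radius = 0.14) {
  ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

# Atom names of the tryptophan side-chain ring system (default quencher
# group).
trp_ring_atoms <- function() {
  c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
}

#' Simulate a minimal labeled-peptide trajectory
#'
#' Builds a synthetic trajectory of a dye-labeled 15-residue peptide
#' reduced to the atoms the analysis protocol touches: a 9-atom fluorophore
#' ring system (residue 0, resname `DYE`), the C-beta atoms of residues 1
#' (Lys) and 14 (Asp), and the 9-atom Trp ring system of residue 15. The
#' fluorophore-Trp ring-center distance follows a planted two-state
#' telegraph process (`dark_sep_nm` when a quenching contact is formed,
#' `bright_sep_nm` otherwise), and the C-beta end-to-end distance follows a
#' planted two-well process, so every downstream classification step has
#' exact ground truth. Frames carry a random rigid rotation/translation.
#'
#' This is synthetic plumbing for pipeline tests, not a physical model of
#' the peptide.
#'
#' @param quench a [telegraph_params()] for the quenching contact dynamics
#'   (its `dt_ns`/`n_steps` set the frame grid).
#' @param two_well optional list of arguments for
#'   [simulate_two_well_distance()] (excluding `dt_ns`, `n_steps`, `seed`);
#'   defaults to wells at 1.0 / 3.0 nm with 1 per-us symmetric hopping.
#' @param dark_sep_nm,bright_sep_nm ring-center separation in the quenched
#'   and fluorescent state (defaults 0.40 / 1.40 nm, straddling the
#'   0.55 nm quenching distance).
#' @param noise_sd_nm Gaussian jitter on ring atom coordinates, nm (kept
#'   small so the state separation is unambiguous).
#' @param seed integer seed.
#' @return a [trajectory_ensemble()]; `truth` carries the underlying
#'   quench [state_sequence()] and two-well series.
#' @export
simulate_peptide_trajectory <- function(quench,
                                        two_well = NULL,
                                        dark_sep_nm = 0.40,
                                        bright_sep_nm = 1.40,
                                        noise_sd_nm = 0.01,
                                        seed = 1L) {
  stopifnot(inherits(quench, "telegraph_params"))
  qs <- simulate_telegraph(quench)
  nf <- length(qs$values)
  tw_args <- c(list(dt_ns = quench$dt_ns, n_steps = nf, seed = seed + 1L),
               if (is.null(two_well)) {
                 list(d_close_nm = 1.0, d_open_nm = 3.0, hop_rates = 1,
                      noise_sd_nm = 0)
               } else two_well)
  tw <- do.call(simulate_two_well_distance, tw_args)
  set.seed(seed + 2L)
  dye_ring <- ring_coords(9L)
  trp_ring <- ring_coords(9L)
  atoms <- rbind(
    data.frame(residue = 0L, resname = "DYE",
               atom = sprintf("C%d", 1:9), element = "C"),
    data.frame(residue = 1L, resname = "LYS", atom = "CB", element = "C"),
    data.frame(residue = 14L, resname = "ASP", atom = "CB", element = "C"),
    data.frame(residue = 15L, resname = "TRP", atom = trp_ring_atoms(),
               element = c(rep("C", 3), "N", rep("C", 5)))
  )
  na <- nrow(atoms)
  frames <- array(0, dim = c(nf, na, 3L))
  sep <- ifelse(qs$values == 1L, bright_sep_nm, dark_sep_nm)
  d_ee <- tw$distance_nm
  for (f in seq_len(nf)) {
    x <- matrix(0, na, 3L)
    x[1:9, ] <- dye_ring                                     # dye ring at origin
    x[12:20, ] <- sweep(trp_ring, 2L, c(sep[f], 0, 0), `+`)  # Trp ring
    x[10, ] <- c(0, 0.8, 0)                                  # CB of Lys1
    x[11, ] <- c(d_ee[f], 0.8, 0)                            # CB of Asp14
    if (noise_sd_nm > 0) {
      x <- x + matrix(rnorm(3L * na, sd = noise_sd_nm), na)
    }
    x <- x %*% t(random_rotation())
    frames[f, , ] <- sweep(x, 2L, rnorm(3L, sd = 1), `+`)
  }
  trajectory_ensemble(atoms, frames[1, , ], frames, quench$dt_ns,
                      truth = list(quench = qs, two_well = tw,
                                   dark_sep_nm = dark_sep_nm,
                                   bright_sep_nm = bright_sep_nm))
}

#' Write / read ensemble frames as a plain multi-frame coordinate table
#'
#' Text interchange format: columns `frame`, `atom`, `x`, `y`, `z` (nm)
#' with a header recording the frame spacing, plus a side-car atom table.
#' The reference structure can be written as PDB via [write_reference_pdb()].
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param path output path for the coordinate table.
#' @export
write_frames_table <- function(ensemble, path) {
  nf <- n_frames(ensemble); na <- nrow(ensemble$atoms)
  df <- data.frame(frame = rep(seq_len(nf), each = na),
                   atom = rep(seq_len(na), nf),
                   x = as.vector(t(ensemble$frames[, , 1])),
                   y = as.vector(t(ensemble$frames[, , 2])),
                   z = as.vector(t(ensemble$frames[, , 3])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# petfcs frames dt_frame_ns=%.10g n_atoms=%d",
                     ensemble$dt_frame_ns, na), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_frames_table
#' @param atoms atom metadata data frame (as in [trajectory_ensemble()]).
#' @param ref reference coordinates; defaults to the first frame.
#' @return for `read_frames_table`, a [trajectory_ensemble()].
#' @export
read_frames_table <- function(path, atoms, ref = NULL) {
  hdr <- readLines(path, n = 1L)
  dt <- as.numeric(sub(".*dt_frame_ns=(\\S+).*", "\\1", hdr))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  na <- nrow(atoms)
  nf <- max(df$frame)
  frames <- array(0, dim = c(nf, na, 3L))
  o <- order(df$frame, df$atom)
  df <- df[o, ]
  frames[, , 1] <- matrix(df$x, nf, na, byrow = TRUE)
  frames[, , 2] <- matrix(df$y, nf, na, byrow = TRUE)
  frames[, , 3] <- matrix(df$z, nf, na, byrow = TRUE)
  if (is.null(ref)) ref <- frames[1, , ]
  trajectory_ensemble(atoms, ref, frames, dt)
}

#' Read / write a reference structure as PDB (via bio3d)
#'
#' @param path PDB file path.
#' @return for `read_reference_pdb`, a list with `atoms` (metadata data
#'   frame) and `ref` (coordinates in nm; PDB Angstroms are converted).
#' @export
read_reference_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("bio3d is required for PDB input")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  atoms <- data.frame(residue = a$resno, resname = a$resid, atom = a$elety,
                      element = ifelse(is.na(a$elesy) | a$elesy == "",
                                       substr(a$elety, 1, 1), a$elesy))
  ref <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  list(atoms = atoms, ref = ref)
}

#' @rdname read_reference_pdb
#' @param ensemble a [trajectory_ensemble()].
#' @param coords `n_atoms x 3` matrix (nm) to write; defaults to the
#'   reference structure.
#' @export
write_reference_pdb <- function(ensemble, path, coords = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("bio3d is required for PDB output")
  }
  if (is.null(coords)) coords <- ensemble$ref
  at <- ensemble$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords)) * 10,
                   resno = at$residue, resid = at$resname, elety = at$atom,
                   chain = "A")
  invisible(path)
}
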