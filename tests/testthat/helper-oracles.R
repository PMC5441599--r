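# Independent oracles and fixture builders used across the suite.

# Base-R Kabsch RMSD (svd route), independent of the compiled kernel.
kabsch_rmsd_r <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  tr <- sum(sv$d * c(1, 1, d))
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * tr) / nrow(A)))
}

# Best RMSD over a coarse grid of rotations (brute force; no SVD), used to
# confirm the Kabsch solution on tiny structures.
grid_rmsd_r <- function(A, B, step_deg = 6) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  ang <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  ang_b <- seq(0, pi, by = step_deg * pi / 180)
  best <- Inf
  for (a in ang) for (b in ang_b) for (g in ang) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    r <- sqrt(mean(rowSums((A %*% t(Rz1 %*% Ry %*% Rz2) - B)^2)))
    if (r < best) best <- r
  }
  best
}

# Analytic normalized autocorrelation of a two-state telegraph emitter:
# G(tau) = 1 + (k_form/k_diss) * exp(-(k_form + k_diss) * tau).
telegraph_g <- function(tau_s, k_form_per_us, k_diss_per_us) {
  k_sum <- (k_form_per_us + k_diss_per_us) * 1e6
  1 + (k_form_per_us / k_diss_per_us) * exp(-k_sum * tau_s)
}

# Connected components of the d < cutoff graph via breadth-first search:
# brute-force single-linkage oracle.
components_bfs <- function(D, cutoff) {
  n <- nrow(D)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(D[v, ] < cutoff & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Two partitions are the same up to relabeling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1L) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1L)
}

# Small planted centers: k well-separated random structures (nm).
make_centers <- function(k, n_atoms = 12, spread = 1.0, seed = 42) {
  set.seed(seed)
  lapply(seq_len(k), function(i) matrix(rnorm(3 * n_atoms, sd = spread),
                                        n_atoms))
}

# Synthetic correlation curve from the pure dynamic model plus Gaussian
# noise with known per-lag sigma.
make_dyn_curve <- function(a, tau_s, sigma = 0.02, n_lags = 64,
                           lag_range = c(1e-8, 1e-4), seed = 1) {
  set.seed(seed)
  lags <- 10^seq(log10(lag_range[1]), log10(lag_range[2]),
                 length.out = n_lags)
  y <- rep(0, n_lags)
  for (i in seq_along(a)) y <- y + a[i] * exp(-lags / tau_s[i])
  correlation_curve(lags, y + rnorm(n_lags, sd = sigma),
                    sigma = rep(sigma, n_lags), convention = "excess")
}
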