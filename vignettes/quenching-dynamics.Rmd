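---
title: "Comparing peptide quenching dynamics between photon streams and trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing peptide quenching dynamics between photon streams and trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petfcs)
```

## The problem

A short intrinsically disordered peptide carrying an oxazine fluorophore at
one terminus and a tryptophan quencher at the other reports its end-to-end
contact dynamics through photoinduced electron transfer (PET): when the two
ring systems come into van-der-Waals contact the fluorescence is switched
off, effectively instantaneously and completely. Fluorescence correlation
spectroscopy (FCS) of such a construct therefore carries, superimposed on
diffusion and photophysics, a bunching term whose amplitude and relaxation
time encode the microscopic rates of quenching-contact formation and
dissociation. The same observable can be computed from an atomistic
trajectory by classifying every frame as dark or fluorescent with a simple
distance criterion and correlating the resulting binary signal. `petfcs`
implements both sides of that comparison as a tested pipeline and exercises
it end to end on synthetic data with known ground truth.

## Models

**Two-state quenching.** The dynamic part of the correlation is the
single-exponential two-state model
$G_\mathrm{dyn}(\tau) = a_r e^{-\tau/\tau_r}$.
Its parameters map to microscopic rates through
$\tau_r = 1/(k_\mathrm{on} + k_\mathrm{off})$ and
$a_r = k_\mathrm{off}/k_\mathrm{on}$,
where $k_\mathrm{on}$ is contact formation and $k_\mathrm{off}$
dissociation. `rates_from_dynamics()` implements this inversion as the
default `"as_printed"` convention, the form rate tables in the PET-FCS
literature use. The closed form of a two-state telegraph emitter, however,
gives a correlation amplitude equal to (dark fraction)/(bright fraction)
$= k_\mathrm{form}/k_\mathrm{diss}$ — the roles of the two rates
exchanged. Both readings are implemented (`"telegraph_oracle"` is the
convention under which rates recovered from simulated telegraph signals
match the simulator inputs); the discrepancy is surfaced in the
documentation rather than silently resolved, and every recovery test in
this package uses the telegraph convention because it is the one the
generative process obeys.

**Composite FCS model.** Experimental-style curves are fit with
$$G(\tau) = \frac{\gamma}{N}\Big(1+\frac{\tau}{\tau_D}\Big)^{-1}
\Big(1+\frac{\tau}{p^2\tau_D}\Big)^{-1/2}
\big(1 - A_{ab} e^{-\tau/\tau_{ab}}\big)
\Big(1 + \frac{T}{1-T} e^{-\tau/\tau_T}\Big)
\Big(1 + \sum_{r} a_r e^{-\tau/\tau_r}\Big),$$
with $\gamma = 2^{-3/2}$ fixed (overridable), diffusion time $\tau_D$,
axial ratio $p$, antibunching amplitude/time $A_{ab}, \tau_{ab}$, triplet
fraction/time $T, \tau_T$, and one or two dynamic terms. The triplet
exponent is implemented in the standard decaying form $e^{-\tau/\tau_T}$; a
growing exponential would be unphysical. The diffusion coefficient follows
from the lateral focal size via $D = w^2/(4\tau_D)$.

**Trajectory protocol.** Frames are classified dark when the unweighted
geometric centers of the fluorophore and quencher ring systems are strictly
closer than $r^* = 0.55$ nm. The end-to-end distance between the C-beta
atoms of residues 1 and 14 defines *close* ($d < 1.3$ nm) and *open*
($d > 2.5$ nm) regimes with strict inequalities; transition counting uses
last-assigned-regime (hysteresis) semantics — intermediate frames keep the
previous regime, every open/close switch counts in $N_T$, and the mean rate
is $N_T$ over the total time. Under this reading the rate is a mean of
opening *and* closing events (1503 transitions in 30 µs give 50.1 µs⁻¹,
the arithmetic the reference values follow); a single-direction reading
would halve it, which those values exclude. Conformational
regimes are clustered by single linkage on the pairwise superposed
heavy-atom RMSD at a 0.25 nm cutoff, clusters numbered by population;
cluster representatives are medoids (minimum summed RMSD), because
averaging coordinates of disordered frames produces unphysical structures.
Superposition before RMSD is applied always — the analyzed selection is
also the fit selection.

## The synthetic-data generators

The generators are first-class, tested code: they define the conditions
under which every stochastic claim in the test suite holds.

* `simulate_telegraph()` draws exact exponential dwell times (initial state
  from the stationary distribution, avoiding equilibration bias) and
  samples the process on a uniform grid. The default recovery fixture uses
  the tabulated data volume — $10^6$ frames spanning 30 µs (30 ps
  spacing) — with rates in the 72 ns relaxation regime.
* `simulate_two_well_distance()` produces a piecewise-constant two-state
  distance with Gaussian observation noise; wells default to clearing the
  regime thresholds by three noise standard deviations so that assignment
  is unambiguous, and the exact hidden jump times are returned.
* `simulate_ensemble()` plants cluster structure: a frame picks a center by
  weight, adds isotropic Gaussian coordinate noise, and is then rigidly
  rotated and translated at random so any clustering must superpose.
  Within one cluster the pairwise superposed RMSD concentrates near
  $\sqrt{2}\,\sigma$; clusters are cleanly separable at cutoff $c$ when
  $3\sqrt{2}\sigma < c$ and center–center RMSDs exceed $2c$.
* `simulate_photons()` runs Brownian emitters in a periodic box around a 3D
  Gaussian detection profile ($w$ = 195 nm lateral). Proposal photons are
  drawn per Brownian step as Poisson thinning of
  $\mathrm{brightness}\times W(x)$; the binary triplet and quenching
  factors are then applied *exactly*, by evaluating the two-state Markov
  transition probabilities at the proposed photon times. Because those
  factors are event-exact, the Brownian step only needs to resolve the
  diffusion time (default $\tau_D/100$, refused above $\tau_D/10$) rather
  than the fastest blinking process. Antibunching, when enabled, delays
  each particle's next photon by an exponential excited-state dwell.
  Timestamps are quantized to the 16 ps recording tick and same-tick
  arrivals on a channel are merged; an optional 50:50 random split emulates
  the beam-splitter arrangement of two detectors.

What the photon generator does *not* emulate: detector afterpulsing and
dead time, background and scatter, vendor TTTR formats, and any
excitation-intensity dependence of the triplet amplitude (the measured
laser-power dependence implies one, but no functional form is available, so
$T$ and $\tau_T$ are direct inputs). Passing recovery tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to these instrumental artifacts.

**Finite periodic box.** In a periodic box the correlation decays to
baseline at the box mixing time (slowest diffusive mode,
$\sim (L/2\pi)^2/D$) instead of following the open-space power-law tail.
The default box (12 lateral focal radii, 6 axial) pushes that time beyond
10 $\tau_D$ laterally, and fits cap the lag range at 10 $\tau_D$; the
residual tail suppression is below the per-lag uncertainty there. Particles
sitting where the detection weight is below $10^{-6}$ advance several
Brownian steps at once (exact Gaussian marginals, capped so one coarse step
stays below $0.35\,w$) — they cannot emit detectably from there, and the
distance to appreciable weight is many coarse-step standard deviations, so
grazing entries are not missed.

## Correlators and uncertainties

`direct_correlation()` evaluates the definition
$G(\tau) = \langle I(t)I(t+\tau)\rangle / \langle I\rangle^2$ by brute
force with *symmetric normalization* (means over the overlapping windows at
each lag), which removes the linear finite-length bias and serves as the
oracle for the multiple-tau correlator. Binary MD-style quenching signals
are correlated this way on a logarithmic lag subset — at $10^6$ samples
exactness is affordable — with lags restricted to at least 100 contributing
products, because the estimate converges poorly at the largest lags.

`multiple_tau_correlation()` implements the classic quasi-logarithmic
scheme (16 lags per level, bin width doubling per level; the lag grid
excludes $\tau = 0$, where shot noise sits). Uncertainties come from
splitting the measurement into ten equal segments and taking the standard
error of the mean per lag. Segment curves for photon streams are normalized
by the *full-measurement* mean rates by default: with per-segment
normalization each segment's mean estimate correlates with its own
fluctuations and biases the curve down by $\approx 2\int G_\mathrm{exc}\,
d\tau / T_\mathrm{seg}$, which at 30 ms segments is comparable to the
diffusion tail being fit. Shared normalization shrinks that bias by the
segment count; per-segment ("symmetric") normalization remains available.

## Fitting

Weighted Levenberg–Marquardt minimizes
$\sum ((G_i - G(\tau_i))/\sigma_i)^2$, with 95% confidence intervals from
the unscaled covariance matrix $(J^\top J)^{-1}$ at the optimum — so
doubling all $\sigma_i$ doubles the interval widths and leaves the point
estimates untouched, and intervals are calibrated when the supplied
$\sigma_i$ are honest (the suite verifies 90–99% empirical coverage on 100
synthetic replicates, and $\geq$ 90% per parameter on 50 full
photon-pipeline replicates). Bounds keep the optimizer physical: times in
$[1\,\mathrm{ps}, 10\,\mathrm{s}]$, amplitudes in $[0, 10]$, $T \in [0,
0.99]$. Initial guesses derive from curve features (small-lag amplitude
$\to \gamma/N$ prefactor, half-decay lag $\to \tau_D$) refined by a small
deterministic multistart over the $\tau_D$ decade; explicit starts can be
supplied. Parameters at bounds and non-convergence are flagged on the
result, never raised as errors.

Because the triplet and quenching factors share one functional form, a fit
with both free is invariant under exchanging their labels. The standard
recovery conditions therefore restrict the triplet time to the microsecond
range and the quenching terms below it — ordinary prior knowledge for
organic dyes — and hold the calibrated axial ratio fixed. One- versus
two-component model choice uses an F-test on the nested chi-squares at
$\alpha = 0.05$ (advisory, threshold configurable), plus a lag-1 residual
autocorrelation diagnostic.

## Problem sizes

The stochastic suites run at sizes chosen to keep the full test suite in
the tens of minutes on one core while leaving comfortable statistical
margins: telegraph recovery uses the tabulated data volume ($10^6$ frames,
20 seeds); photon-pipeline recovery uses 50 replicates of 0.3 s synthetic
measurements (about $10^5$ photons each) with quenching slowed to a 200 ns
relaxation so that a quarter-second record resolves every process with
well-separated timescales ($\tau_r : \tau_T : \tau_D \approx 1 : 12 :
250$); clustering correctness uses ensembles of up to $2\times10^3$ frames
where the brute-force connected-components oracle is exact. The
experimental values themselves (16 h of photons, 30 µs of all-atom
trajectory) are inputs this package cannot regenerate; the recovery suites
are property-based stand-ins at reduced scale.

## Design choices and limitations

* Single linkage is exact connected components of the strict
  $d < \mathrm{cutoff}$ graph; beyond 3000 frames a pivot-based
  triangle-inequality bound prunes candidate pairs (RMSD on superposed
  selections is a pseudo-metric), with identical output and a desk-scale
  refusal above $2\times10^4$ frames.
* The fluorophore ring-atom group has no standard naming across topologies
  and must be supplied; the Trp side-chain ring
  (CG, CD1, CD2, NE1, CE2, CE3, CZ2, CZ3, CH2) is the default quencher
  group.
* Coordinates are nm and residue indices 1-based throughout; lag times are
  seconds internally, with ns/µs appearing only at interface boundaries.
* The minimal labeled-peptide trajectory generator is synthetic plumbing —
  it reproduces the geometry the classification steps touch (ring centers,
  terminal C-beta atoms) with planted dynamics, not peptide physics.
* `isolate_dynamic()` divides out the full non-dynamic model including the
  $\gamma/N$ prefactor; the two-component summary uses the
  amplitude-weighted mean relaxation time by default (arithmetic mean by
  flag) — the averaging weights are a genuine ambiguity and the choice is
  recorded on the result.

## A worked example

```{r example, eval = FALSE}
# simulation-side: planted telegraph quenching in a minimal trajectory
q <- telegraph_params(k_form = 8.4, k_diss = 5.5, dt_ns = 30,
                      n_steps = 6e5, seed = 11)
en <- simulate_peptide_trajectory(q, noise_sd_nm = 0.005, seed = 12)
res <- run_md_pipeline(en, config = list(
  criterion = quench_criterion(group_A = list(residue = 0L,
                                              atoms = sprintf("C%d", 1:9))),
  equilibration_offset_s = 0.4 * duration_s(en$truth$quench),
  convention = "telegraph_oracle"))
comparison_report(md = res)

# experiment-side: synthetic photon stream through the FCS pipeline
rc <- fcs_recovery_conditions(seed = 1)
fcs <- run_fcs_pipeline(rc$sim, rc$config)
comparison_report(fcs = fcs)
```

The numbered scripts under `analysis/` run these analyses with narrative
output and write their tables under `results/`.
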