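# petfcs

Analysis toolkit for comparing the end-to-end quenching dynamics of a
fluorescently labeled peptide between single-molecule PET-FCS measurements
and molecular-dynamics trajectories.

## The problem

A short disordered peptide carrying an oxazine dye at one terminus and a
tryptophan at the other is switched dark whenever dye and quencher form a
van-der-Waals contact (photoinduced electron transfer, an effectively
all-or-nothing process). Two very different experiments observe the same
two-state kinetics:

* **PET-FCS**: the correlation function of detected photons carries a
  bunching term `G_dyn(tau) = a_r * exp(-tau/tau_r)` on top of diffusion,
  triplet blinking and antibunching;
* **MD**: classifying every trajectory frame as dark (fluorophore/quencher
  ring centers closer than r* = 0.55 nm) or fluorescent gives a binary
  signal whose autocorrelation is fit by the same model.

In both cases the fitted amplitude and relaxation time convert to
microscopic contact formation and dissociation rates through

    tau_r = 1 / (k_on + k_off),        a_r = k_off / k_on.

`petfcs` implements the full protocol on both sides — exact two-state and
confocal photon-stream simulators with known ground truth, direct and
multiple-tau correlators with ten-segment standard errors, weighted fits of
the composite FCS model

    G(tau) = gamma/N * (1 + tau/tau_D)^-1 * (1 + tau/(p^2 tau_D))^-1/2
             * (1 - A_ab e^(-tau/tau_ab)) * (1 + T/(1-T) e^(-tau/tau_T))
             * (1 + sum_r a_r e^(-tau/tau_r)),    gamma = 2^(-3/2),

one- vs two-component model comparison, isolation of the dynamic part, and
trajectory post-processing (Kabsch-superposed RMSD, single-linkage
clustering at a 0.25 nm cutoff, end-to-end distance regimes at 1.3/2.5 nm
with transition-rate statistics, quench classification and its
autocorrelation).

## Worked example

Simulation side — a synthetic labeled-peptide trajectory whose
quenching-contact dynamics follow a planted telegraph process with
k_on = 8.4, k_off = 5.5 per microsecond (71.9 ns relaxation):

```r
library(petfcs)
q  <- telegraph_params(k_form = 8.4, k_diss = 5.5, dt_ns = 30,
                       n_steps = 6e5, seed = 11)
en <- simulate_peptide_trajectory(q, noise_sd_nm = 0.005, seed = 12)
res <- run_md_pipeline(en, config = list(
  criterion = quench_criterion(group_A = list(residue = 0L,
                                              atoms = sprintf("C%d", 1:9))),
  equilibration_offset_s = 0.4 * duration_s(en$truth$quench),
  convention = "telegraph_oracle"))
```

prints (via `analysis/04_trajectory_analysis.R`):

```
full window:    a_r = 1.53, tau_r = 72 ns
post-eq window: a_r = 1.52, tau_r = 72 ns (truth 1.53, 72)
rates: k_on = 8.4, k_off = 5.5 us^-1 (truth 8.4, 5.5)
```

The amplitude is the dark/bright population ratio, the relaxation time the
inverse summed rate, and the converted rates recover the generator exactly
within sampling error.

Experiment side — a quarter second of synthetic two-channel photon
detection (diffusing emitters, triplet blinking, two-state quenching)
through the FCS pipeline:

```r
rc  <- fcs_recovery_conditions(seed = 1)
fcs <- run_fcs_pipeline(rc$sim, rc$config)
```

prints (via `analysis/03_photon_fcs_pipeline.R`):

```
photons detected: 172215
fitted tau_D = 51.2 us (truth 50.0 us)
fitted triplet: T = 0.27, tau_T = 2.69 us (truth 0.25, 2.40)
dynamic term: a_r = 0.83, tau_r = 188 ns (truth 1.00, 200)
model comparison: 1 component(s) preferred (F p = 1)
rates (telegraph_oracle): k_on = 2.41, k_off = 2.91 us^-1 (truth 2.5, 2.5)
```

Each fitted parameter sits inside its 95% confidence interval; across 50
seeded replicates the per-parameter coverage is at least 90% (verified in
the test suite).

The numbered scripts under `analysis/` run the full set of analyses —
rate-table conversions, telegraph recovery at the 10^6-frame data volume,
the photon pipeline, and clustering/transition statistics on planted
ensembles — and write their tables under `results/`.

## Layout

```
R/                  package code: simulators, correlators, models,
                    fitting, trajectory analysis, pipelines
src/                compiled kernels (Kabsch RMSD, Brownian photon proposals)
analysis/           numbered narrative analysis scripts
scripts/            acceptance script
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, assumptions, design choices)
```
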