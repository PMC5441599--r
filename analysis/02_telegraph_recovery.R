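#!/usr/bin/env Rscript
# Recovery of two-state quenching kinetics from sampled binary signals.
#
# Simulates contact formation/dissociation telegraph signals at the data
# volume of a long atomistic trajectory (10^6 frames spanning 30 us),
# computes the quenching autocorrelation, fits the single-exponential
# two-state model, and converts back to rates. The fitted relaxation time
# must approach 1/(k_form + k_diss) and the amplitude k_form/k_diss.

library(petfcs)
dir.create("results", showWarnings = FALSE)

k_form <- 8.4; k_diss <- 5.5        # per us; 71.9 ns relaxation regime
n_seeds <- 5

rows <- lapply(seq_len(n_seeds), function(seed) {
  tp <- telegraph_params(k_form, k_diss, dt_ns = 0.03, n_steps = 1e6,
                         seed = seed)
  s <- simulate_telegraph(tp)
  qa <- quench_autocorrelation(s, convention = "telegraph_oracle")
  data.frame(seed = seed, a_r = qa$fit$a_r,
             tau_r_ns = qa$fit$tau_r_s * 1e9,
             k_on_per_us = qa$fit$rates$k_on_per_us,
             k_off_per_us = qa$fit$rates$k_off_per_us)
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
cat(sprintf(
  "truth: a_r = %.3f, tau_r = %.1f ns, k_on = %.1f, k_off = %.1f us^-1\n",
  k_form / k_diss, 1e3 / (k_form + k_diss), k_form, k_diss))
cat(sprintf("mean recovered: a_r = %.3f, tau_r = %.1f ns\n",
            mean(tab$a_r), mean(tab$tau_r_ns)))
write.csv(tab, "results/telegraph_recovery.csv", row.names = FALSE)
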