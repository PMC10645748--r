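#!/usr/bin/env Rscript

# Quantal sparklet activity and coupled gating.
#
# Simulates sparklet sites across the coupling range (kappa 0 to 1) with the
# coupled Markov chain, idealizes the noisy fluorescence traces into quantal
# levels, computes site activity (nPs, 0.2 low/high cutoff), and re-estimates
# kappa by maximum likelihood — the full inference chain a recorded trace
# would pass through, here with known ground truth.

library(kvclust)

seed <- 303L
dir.create("results", showWarnings = FALSE)

kappas <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
n_rep <- 10L
rows <- list()
for (k in kappas) {
  for (r in seq_len(n_rep)) {
    sim <- gen_sparklet_trace(sparklet_spec(
      3, k, 0.1, quantal_amplitude = 1, noise_sd = 0.2, duration = 20,
      seed = derive_seed(seed, sprintf("site-%g-%d", k, r))))
    rec <- detect_and_idealize(sim$trace, quantal_config(1, max_levels = 3))
    act <- compute_nps(rec)
    est <- estimate_kappa(rec, 3)
    rows[[length(rows) + 1L]] <- data.frame(
      kappa_true = k, replicate = r,
      frame_accuracy = mean(rec$levels == sim$record$levels),
      nPs = act$nPs, activity_class = act$activity_class,
      kappa_hat = est$kappa, open_prob_hat = est$open_prob)
  }
}
tab <- do.call(rbind, rows)
agg <- aggregate(cbind(kappa_hat, nPs, frame_accuracy) ~ kappa_true, tab,
                 mean)
cat("mean estimates by true coupling:\n")
print(agg, row.names = FALSE)

write.csv(tab, "results/sparklet_recovery.csv", row.names = FALSE)
cat("wrote results/sparklet_recovery.csv\n")
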