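#!/usr/bin/env Rscript
# Monte-Carlo motif-recovery experiment: 50 independently seeded
# replicates of the default simulation condition, full pipeline per
# replicate, reporting how often the rank-1 window recovers the planted
# block (Jaccard >= 0.5) and the score contrast inside vs outside it.
# Takes about a minute.

library(consmotif)

cfg <- sim_config(n_taxa = 24, n_codons = 200, tree_length = 2,
                  omega_background = 1, motif_omega = 0.02,
                  motif_syn_scale = 0.1, seed = 20240601L)
res <- recovery_experiment(cfg, n_reps = 50, w = 21, jaccard_min = 0.5)

dir.create("results/recovery", showWarnings = FALSE, recursive = TRUE)
write_tsv_commented(
  data.frame(replicate = seq_along(res$recovered),
             recovered = res$recovered),
  "results/recovery/replicates.tsv")

cat("Replicates:", length(res$recovered),
    "| failures:", length(res$errors), "\n")
cat("Recovery fraction (Jaccard >= 0.5):", res$fraction, "\n")
cat("Mean score inside planted block:", round(res$mean_score_inside, 3),
    "| outside:", round(res$mean_score_outside, 3), "\n")
cat("\nNote: with a fully neutral background the planted block is found",
    "mainly through residue identity; its dN-dS is ~0 (both substitution",
    "classes are suppressed), so the selection component contributes",
    "little - see the methods vignette for the full discussion.\n")
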