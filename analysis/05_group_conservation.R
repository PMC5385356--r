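#!/usr/bin/env Rscript
# Cross-group conservation categorization: per-position within-group
# identity flags on the simulated 5-group ortholog set, the nested
# category bands, and the published endospanin band arithmetic
# (1/13/16/45 over 140 positions) reproduced through the same code path.

library(consmotif)

orfs <- read_orfs("results/sim/orfs.fasta")
gt <- read_groups("results/sim/groups.tsv", orfs$id)
aln <- build_reference_alignment(orfs, ref_id = orfs$id[1])

prof <- group_conservation_profile(alignment_aa_matrix(aln), gt)
pct <- category_percentages(prof, ncol(aln$codons))

dir.create("results/groups", showWarnings = FALSE, recursive = TRUE)
write_tsv_commented(
  data.frame(position = aln$aa_start:aln$aa_end,
             n_groups_conserved = prof$n_groups_conserved,
             category = prof$category),
  "results/groups/per_position.tsv")
write_tsv_commented(pct, "results/groups/band_summary.tsv")

cat("Simulated 5-group set:\n")
print(pct, row.names = FALSE)
cat("Any-band total:", attr(pct, "total_rounded"),
    "% (rounded-band sum);", attr(pct, "total_exact"), "% exact\n\n")

# the published endospanin arithmetic through category_percentages
pub <- category_percentages(c(1, 13, 16, 45), 140)
cat("Published endospanin accounting (counts 1/13/16/45 over 140):\n")
print(pub, row.names = FALSE)
cat("Any-band total:", attr(pub, "total_rounded"), "%\n")
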