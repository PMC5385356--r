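#!/usr/bin/env Rscript
# Generate the synthetic ortholog set the rest of the workflow analyzes:
# 24 taxa, 200 codons on a balanced tree of total length 2 substitutions
# per nucleotide site, one centered 21-codon planted invariant motif
# (positions 90-110), five labeled organism groups. Writes the FASTA,
# group table and simulation truth under results/sim/.

library(consmotif)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_taxa = 24, n_codons = 200, tree_length = 2,
                  n_groups = 5, seed = 20240601L)
sim <- simulate_alignment(cfg)

write_orfs(sim$orfs, file.path(out, "orfs.fasta"))
writeLines(paste(sim$truth$groups$id, sim$truth$groups$group, sep = "\t"),
           file.path(out, "groups.tsv"))
writeLines(sim$truth$newick, file.path(out, "true_tree.nwk"))
write_tsv_commented(
  data.frame(position = seq_along(sim$truth$omega),
             omega = sim$truth$omega),
  file.path(out, "true_omega.tsv"))
write_tsv_commented(
  do.call(rbind, lapply(sim$truth$motif_intervals, function(iv)
    data.frame(start = iv[1], end = iv[2]))),
  file.path(out, "true_motifs.tsv"))

cat("Simulated", nrow(sim$orfs), "in-frame ORFs of",
    cfg$n_codons, "codons; planted motif at",
    paste(sim$truth$motif_intervals[[1]], collapse = "-"), "\n")
cat("Outputs in", out, "\n")
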