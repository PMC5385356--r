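# consmotif

Reference-anchored conservation profiling and linear-motif discovery for
protein-coding ortholog sets.

Given a multi-FASTA of in-frame ORFs for one gene family (e.g., the leptin
pathway genes LEP, LEPR, LEPROT and their vertebrate/invertebrate
orthologs) and the id of a reference sequence (the human ortholog),
`consmotif` answers: *where along the protein do residue conservation and
purifying selection concentrate, which contiguous 21-codon stretches look
like conserved linear motifs, how do the sequences relate phylogenetically,
and which positions stay conserved across higher-order organism groups?*

The core statistic is a per-site 0–2 conservation score

```
score_i = c_i + clamp(z_i / 2, 0, 1)
```

where `c_i = (m_i − 1)/(n_i − 1)` is the residue-identity component (modal
residue count `m` among `n` non-gap residues: 1 at 100% identity, 0 when
all residues differ) and `z_i` is the within-gene standardization of
`d_i = dN_i − dS_i` from Nei–Gojobori-style pathway counting, sign-flipped
so purifying selection is positive. A score of 2 therefore requires both
100% residue identity and selection more than 2 SDs above the gene mean;
a score of 0 requires no conservation and at-or-below-mean selective
pressure. Scores are averaged over sliding 21-codon windows and the top
non-overlapping windows are reported as motifs, with all coordinates in
reference (human) protein numbering.

Around that core the package provides: a protein-guided star codon
aligner (`build_reference_alignment`), TN93 distances + neighbor-joining
trees with bootstrap supports (`tn93_matrix`, `nj_tree`,
`bootstrap_supports`), cross-group conservation categorization
(`group_conservation_profile`, `category_percentages`), a codon-evolution
simulator with site-specific ω and planted invariant motifs
(`simulate_alignment`), and an end-to-end driver (`run_pipeline`).

## Worked example

The `analysis/` directory is a numbered workflow over simulated data with
known ground truth. `analysis/01_simulate_data.R` generates 24 ORFs of
200 codons on a balanced tree (total length 2 substitutions/site) with an
invariant 21-codon block planted at positions 90–110, and
`analysis/03_selection_and_motifs.R` runs the scoring stack on it:

```
Top motifs (21-codon windows, reference numbering):
 rank start end window_mean
    1    90 110    1.084524
    2    46  66    1.063343

Planted motif 90-110; rank-1 window 90-110 (Jaccard 1.00)
Mean score inside planted block: 1.085 | outside: 0.867
```

The rank-1 window lands exactly on the planted block; its mean score ≈ 1.1
(residue identity ≈ 1 plus a small selection component) against a neutral
background ≈ 0.87. `analysis/04_phylogeny.R` rebuilds the tree from TN93
distances:

```
TN93 distance range: 0.0519 - 0.4039 substitutions/site
Bootstrap replicates used: 500
Internal-edge supports: median 100 | >= 95: 21 of 21
Robinson-Foulds distance to the true tree: 0
```

i.e., the true 24-taxon topology is recovered exactly with full bootstrap
support. `analysis/05_group_conservation.R` reproduces the published
five-group endospanin accounting (band counts 1/13/16/45 over 140
positions → 0.7 / 9.3 / 11.4 / 32.1%, total 53.5%), and
`analysis/06_motif_recovery.R` runs the 50-replicate recovery experiment
(see the methods vignette for why a fully neutral background is the hard
case for the additive score).

Typical interactive use on your own data:

```r
library(consmotif)
orfs <- read_orfs("lep_orfs.fasta")
res  <- run_pipeline(orfs, ref_id = "human_LEP", out_dir = "lep_run",
                     aa_start = 22, aa_end = 167, k = 2, boot = 500,
                     seed = 17, groups = "groups.tsv")
res$motifs          # ranked 21-codon motif windows
res$tree            # NJ tree with bootstrap node labels
```

## Layout

```
R/                  package code (alignment, selection, scoring, motifs,
                    phylogeny, group conservation, simulator, pipeline)
analysis/           numbered workflow scripts writing under results/
scripts/acceptance.R  headline-quantity reproduction (JSON output)
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, parameters, design notes)
```
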