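#' Run the full conservation-motif pipeline
#'
#' End-to-end driver: reads (or takes) an ORF set, builds the
#' reference-anchored codon alignment, computes the per-site selection
#' profile and 0-2 conservation scores, extracts the top sliding-window
#' motifs, builds the TN93 + neighbor-joining tree with bootstrap
#' supports, and (when a group table is supplied) the cross-group
#' conservation categorization. All outputs are written as
#' commented-header TSV, FASTA or Newick under `out_dir`, together with a
#' `manifest.tsv` recording the configuration and seed; the run is
#' deterministic given the seed. A stage failure leaves the completed
#' stage outputs in place and an `ERROR.txt` naming the failed stage.
#'
#' @param orfs An `orf_set`, or a path to a FASTA file.
#' @param ref_id Reference (human ortholog) sequence id.
#' @param out_dir Output directory (created if needed).
#' @param aa_start,aa_end Reference codon range (defaults: full reference).
#' @param w Sliding-window width in codons (default 21).
#' @param k Number of motifs to report (default 2).
#' @param boot Bootstrap replicates (default 500).
#' @param seed Integer seed for the bootstrap resampling.
#' @param groups Optional `group_table` or path to a group TSV.
#' @param min_pairs Minimum codon pairs for a site to be scored.
#' @return Invisibly, a list with the alignment, selection profile,
#'   conservation profile, motif table, tree, and (optional) group
#'   profile.
#' @export
run_pipeline <- function(orfs, ref_id, out_dir, aa_start = 1L,
                         aa_end = NULL, w = 21L, k = 2L, boot = 500L,
                         seed = 1L, groups = NULL, min_pairs = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  res <- list()
  on.exit({
    if (!is.null(stage)) {
      writeLines(paste0("pipeline failed at stage: ", stage),
                 file.path(out_dir, "ERROR.txt"))
    }
  })
  if (is.character(orfs)) orfs <- read_orfs(orfs)
  if (is.character(groups)) groups <- read_groups(groups, orfs$id)
  if (!ref_id %in% orfs$id) {
    stop("reference id '", ref_id, "' not in the ORF set; pass the id of ",
         "the reference (human) ortholog as ref_id", call. = FALSE)
  }

  stage <- "align"
  aln <- build_reference_alignment(orfs, ref_id, aa_start = aa_start,
                                   aa_end = aa_end)
  write_alignment(aln, file.path(out_dir, "codon_alignment.fasta"),
                  file.path(out_dir, "protein_alignment.fasta"))
  res$alignment <- aln

  stage <- "selection"
  sel <- site_selection_profile(aln, min_pairs = min_pairs)
  write_tsv_commented(sel, file.path(out_dir, "site_selection.tsv"))
  res$selection <- sel

  stage <- "score"
  prof <- site_scores(aln, sel)
  write_tsv_commented(prof, file.path(out_dir, "site_scores.tsv"))
  res$scores <- prof

  stage <- "motifs"
  motifs <- top_motifs(window_scores(prof, w = w), k = k)
  write_tsv_commented(motifs, file.path(out_dir, "motifs.tsv"))
  res$motifs <- motifs

  stage <- "tree"
  D <- tn93_matrix(aln)
  write_phylip(D, file.path(out_dir, "distances.phy"))
  tree <- bootstrap_supports(aln, n_reps = boot, seed = seed)
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  res$tree <- tree

  if (!is.null(groups)) {
    stage <- "groups"
    gprof <- group_conservation_profile(alignment_aa_matrix(aln), groups)
    gsum <- category_percentages(gprof, ncol(aln$codons))
    write_tsv_commented(
      data.frame(position = aln$aa_start:aln$aa_end,
                 n_groups_conserved = gprof$n_groups_conserved,
                 category = gprof$category),
      file.path(out_dir, "group_conservation.tsv"))
    write_tsv_commented(gsum, file.path(out_dir, "group_summary.tsv"))
    res$group_profile <- gprof
    res$group_summary <- gsum
  }

  stage <- "manifest"
  manifest <- data.frame(
    key = c("ref_id", "aa_start", "aa_end", "window", "k", "boot", "seed",
            "min_pairs", "n_sequences", "codons_analyzed", "package_version"),
    value = c(ref_id, aln$aa_start, aln$aa_end, w, k, boot, seed, min_pairs,
              nrow(aln$codons), codons_analyzed(aln),
              as.character(utils::packageVersion("consmotif"))))
  write_tsv_commented(manifest, file.path(out_dir, "manifest.tsv"))

  stage <- NULL  # success: no ERROR.txt
  invisible(res)
}
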