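#' Pairwise protein-guided codon alignment
#'
#' Globally aligns a query ORF to a reference ORF at the protein level
#' (Needleman-Wunsch with affine gaps on translated sequences) and
#' back-threads the result to codons: each aligned amino-acid pair or gap
#' maps to the underlying codon triplet or to the gap symbol `"---"`.
#' Aligning translations rather than nucleotides preserves reading frame by
#' construction.
#'
#' @param query,ref Single rows of an `orf_set` (or any list/data.frame row
#'   with `id` and `seq`).
#' @param gap_open,gap_extend Affine gap penalties for the protein
#'   alignment; opening is penalized much more than extension so indels
#'   stay contiguous.
#' @param submat Name of the protein substitution matrix (any matrix
#'   shipped with Biostrings, default `"BLOSUM62"`).
#' @return A list with `query_codons` and `ref_codons`: equal-length
#'   character vectors of codons or `"---"`.
#' @export
pairwise_codon_align <- function(query, ref, gap_open = 10, gap_extend = 0.5,
                                 submat = "BLOSUM62") {
  if (!nzchar(query$seq) || !nzchar(ref$seq)) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  qcod <- split_codons(query$seq)
  rcod <- split_codons(ref$seq)
  qaa <- translate_orf(query$seq)
  raa <- translate_orf(ref$seq)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(qaa),
    subject = Biostrings::AAString(raa),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qi <- 0L
  ri <- 0L
  qout <- character(length(qa))
  rout <- character(length(ra))
  for (k in seq_along(qa)) {
    if (qa[k] == "-") {
      qout[k] <- "---"
    } else {
      qi <- qi + 1L
      qout[k] <- qcod[qi]
    }
    if (ra[k] == "-") {
      rout[k] <- "---"
    } else {
      ri <- ri + 1L
      rout[k] <- rcod[ri]
    }
  }
  list(query_codons = qout, ref_codons = rout)
}

#' Build a reference-anchored star codon alignment
#'
#' Aligns every query ORF pairwise to the reference ORF and assembles a
#' fixed-width codon matrix whose columns are the reference codon positions
#' `aa_start..aa_end` (1-based, inclusive, numbered on the reference full
#' protein). Query codons inserted relative to the reference are dropped
#' (counted per sequence); query positions deleted relative to the
#' reference appear as `"---"`. Rows are ordered reference first, then the
#' remaining ids sorted, so the result is independent of input order.
#'
#' @param orfs An `orf_set`.
#' @param ref_id Id of the reference record (must be present).
#' @param aa_start,aa_end 1-based inclusive codon range on the reference
#'   protein; `aa_end = NULL` means the last reference codon.
#' @param ... Passed to [pairwise_codon_align()].
#' @return A `codon_alignment`: list with `ref_id`, `aa_start`, `aa_end`,
#'   `ids`, `codons` (character matrix, rows = sequences, columns =
#'   reference positions, dimnames set) and `dropped_insertions` (named
#'   integer vector of inserted codons discarded per query).
#' @export
build_reference_alignment <- function(orfs, ref_id, aa_start = 1L,
                                      aa_end = NULL, ...) {
  if (!ref_id %in% orfs$id) {
    stop("reference id '", ref_id, "' not found in the ORF set",
         call. = FALSE)
  }
  ref <- orfs[orfs$id == ref_id, ]
  nref <- nchar(ref$seq) %/% 3L
  if (is.null(aa_end)) aa_end <- nref
  aa_start <- as.integer(aa_start)
  aa_end <- as.integer(aa_end)
  if (aa_start < 1L || aa_end > nref || aa_start > aa_end) {
    stop("invalid reference codon range ", aa_start, "..", aa_end,
         " for a reference of ", nref, " codons", call. = FALSE)
  }
  others <- sort(setdiff(orfs$id, ref_id))
  ids <- c(ref_id, others)
  npos <- aa_end - aa_start + 1L
  codons <- matrix("---", nrow = length(ids), ncol = npos,
                   dimnames = list(ids, as.character(aa_start:aa_end)))
  codons[1L, ] <- split_codons(ref$seq)[aa_start:aa_end]
  dropped <- setNames(integer(length(others)), others)
  for (id in others) {
    q <- orfs[orfs$id == id, ]
    pa <- pairwise_codon_align(q, ref, ...)
    insert <- pa$ref_codons == "---"
    dropped[[id]] <- sum(insert)
    qrow <- pa$query_codons[!insert]    # one query codon/gap per ref position
    codons[id, ] <- qrow[aa_start:aa_end]
  }
  structure(
    list(ref_id = ref_id, aa_start = aa_start, aa_end = aa_end,
         ids = ids, codons = codons, dropped_insertions = dropped),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment: ", nrow(x$codons), " sequences x ", ncol(x$codons),
      " reference positions (", x$aa_start, "..", x$aa_end, " on ",
      x$ref_id, ")\n", sep = "")
  cat("codons analyzed:", codons_analyzed(x), "\n")
  invisible(x)
}

#' Total codon cells examined in an alignment
#'
#' The accounting statistic reported per gene: number of rows times number
#' of reference positions, gap cells included.
#'
#' @param aln A `codon_alignment`.
#' @return An integer, `n_rows * n_positions`.
#' @export
codons_analyzed <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  nrow(aln$codons) * ncol(aln$codons)
}

#' Amino-acid view of a codon alignment
#'
#' Translates each non-gap codon cell; gaps become `"-"`.
#'
#' @param aln A `codon_alignment`.
#' @return Character matrix of one-letter residues and `"-"`.
#' @export
alignment_aa_matrix <- function(aln) {
  aas <- codon_aas()
  m <- aln$codons
  out <- matrix("-", nrow(m), ncol(m), dimnames = dimnames(m))
  idx <- codon_index(m)
  ok <- !is.na(idx)
  out[ok] <- aas[idx[ok]]
  out
}

#' Nucleotide view of a codon alignment
#'
#' Expands each codon column into three nucleotide columns; gap codons
#' become three `"-"` characters. Used for TN93 distances and bootstrap
#' resampling.
#'
#' @param aln A `codon_alignment`.
#' @return Character matrix with `3 * n_positions` columns.
#' @export
alignment_nuc_matrix <- function(aln) {
  m <- aln$codons
  n <- nrow(m)
  p <- ncol(m)
  out <- matrix("-", n, 3L * p, dimnames = list(rownames(m), NULL))
  for (k in 1:3) {
    out[, seq(k, 3L * p, by = 3L)] <- substr(m, k, k)
  }
  out
}

#' Write a codon alignment as gapped FASTA
#'
#' Emits both the gapped codon alignment and, optionally, the aligned
#' protein view.
#'
#' @param aln A `codon_alignment`.
#' @param path Output FASTA path for the codon alignment.
#' @param protein_path Optional path for the aligned protein FASTA.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, protein_path = NULL) {
  seqs <- apply(aln$codons, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = 20001L)
  if (!is.null(protein_path)) {
    aa <- apply(alignment_aa_matrix(aln), 1L, paste, collapse = "")
    Biostrings::writeXStringSet(Biostrings::BStringSet(aa), protein_path,
                                width = 20001L)
  }
  invisible(path)
}
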