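# Shared fixture builders: everything is generated in code at test time.

# a random in-frame ORF of n sense codons (no stops anywhere)
random_orf_seq <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(
    as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0), c("A", "C", "G", "T"), paste0)),
    c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# write a FASTA file from named sequences, return its path
write_fasta_tmp <- function(seqs, wrap = FALSE) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    if (wrap) {
      starts <- seq(1, nchar(s), by = 60)
      writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  path
}

# write a group TSV, return its path
write_groups_tmp <- function(ids, groups, header = FALSE) {
  path <- tempfile(fileext = ".tsv")
  lines <- paste(ids, groups, sep = "\t")
  if (header) lines <- c("id\tgroup", lines)
  writeLines(lines, path)
  path
}

# drop codon `pos` from an in-frame sequence
drop_codon <- function(seq, pos) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(codons[-pos], collapse = "")
}

# insert codon `cod` after position `pos`
insert_codon <- function(seq, pos, cod) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(c(codons[seq_len(pos)], cod,
          codons[seq(pos + 1, length(codons))]), collapse = "")
}

# hand-built codon_alignment from a codon matrix (rows = ids)
manual_alignment <- function(codons, ref_id = rownames(codons)[1],
                             aa_start = 1L) {
  structure(
    list(ref_id = ref_id, aa_start = aa_start,
         aa_end = aa_start + ncol(codons) - 1L,
         ids = rownames(codons), codons = codons,
         dropped_insertions = integer(0)),
    class = "codon_alignment"
  )
}
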