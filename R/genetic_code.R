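#' Genetic-code lookup tables
#'
#' Internal helpers around the standard genetic code (NCBI translation
#' table 1), shared by translation, NG86 site counting and the codon
#' simulator. All tables are keyed by the 64 codons in a fixed order so
#' that codon indices can be used for fast matrix lookups.
#'
#' @name genetic-code
#' @keywords internal
NULL

.nucs <- c("A", "C", "G", "T")

#' All 64 codons in fixed lexicographic order (A < C < G < T)
#' @keywords internal
#' @noRd
all_codons <- function() {
  if (is.null(.consmotif_cache$codons)) {
    .consmotif_cache$codons <- as.vector(
      outer(outer(.nucs, .nucs, paste0), .nucs, paste0)
    )
  }
  .consmotif_cache$codons
}

#' Amino acid for each codon (stops are "*"), in all_codons() order
#' @keywords internal
#' @noRd
codon_aas <- function() {
  if (is.null(.consmotif_cache$aas)) {
    gc <- Biostrings::GENETIC_CODE
    .consmotif_cache$aas <- unname(gc[all_codons()])
  }
  .consmotif_cache$aas
}

.stop_codons <- c("TAA", "TAG", "TGA")

is_stop_codon <- function(codon) codon %in% .stop_codons

sense_codons <- function() setdiff(all_codons(), .stop_codons)

#' Map codon strings to indices in all_codons() order (NA if not a codon)
#' @keywords internal
#' @noRd
codon_index <- function(codons) match(codons, all_codons())

#' Is a single-nucleotide change a transition (A<->G or C<->T)?
#' @keywords internal
#' @noRd
is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Split an in-frame nucleotide string into codons
#' @keywords internal
#' @noRd
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate an in-frame coding sequence
#'
#' Translates a nucleotide sequence codon-by-codon under the standard
#' genetic code. The sequence must be in frame (length a multiple of 3)
#' and contain no ambiguity codes; an internal stop codon is an error
#' because downstream selection counting assumes sense codons throughout.
#'
#' @param seq A nucleotide string over `A`, `C`, `G`, `T` whose length is a
#'   multiple of 3.
#' @return A string of one-letter amino acids, one per codon.
#' @examples
#' translate_orf("ATGAAA") # "MK"
#' @export
translate_orf <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  codons <- split_codons(seq)
  idx <- codon_index(codons)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("invalid or ambiguous codon '", codons[bad], "' at codon ", bad,
         call. = FALSE)
  }
  aa <- codon_aas()[idx]
  if (any(aa == "*")) {
    bad <- which(aa == "*")[1L]
    stop("internal stop codon '", codons[bad], "' at codon ", bad,
         call. = FALSE)
  }
  paste(aa, collapse = "")
}
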