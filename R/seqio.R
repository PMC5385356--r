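#' Read and validate a set of open reading frames from FASTA
#'
#' Reads a multi-FASTA of coding-strand, in-frame ORF nucleotide sequences
#' and applies the validation rules the downstream codon analyses assume:
#' sequences are upper-cased, `U` is mapped to `T`, a trailing stop codon
#' (`TAA`/`TAG`/`TGA`) is stripped, and a record is rejected (with a
#' warning, the run continues) if its length is not a multiple of 3, if it
#' contains ambiguity codes, or if an in-frame internal stop remains.
#' Duplicate identifiers and empty files are hard errors.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return An `orf_set`: a `data.frame` with columns `id` and `seq`, one row
#'   per accepted record, with attributes `stripped_stop` (ids whose trailing
#'   stop was removed) and `rejected` (ids of rejected records).
#' @seealso [write_orfs()], [translate_orf()]
#' @export
read_orfs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(xs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  orf_set(ids, seqs)
}

#' Build a validated ORF set from ids and sequences
#'
#' The programmatic counterpart of [read_orfs()]: applies the same
#' normalization and record-level validation to in-memory sequences.
#'
#' @param ids Character vector of unique, non-empty record identifiers.
#' @param seqs Character vector of nucleotide sequences, parallel to `ids`.
#' @return An `orf_set` data.frame (see [read_orfs()]).
#' @export
orf_set <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (any(!nzchar(ids))) stop("empty sequence id", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence id(s)", call. = FALSE)
  seqs <- gsub("U", "T", toupper(seqs), fixed = TRUE)
  keep <- logical(length(ids))
  stripped <- character(0)
  for (i in seq_along(ids)) {
    s <- seqs[i]
    if (!grepl("^[ACGT]*$", s)) {
      warning("record '", ids[i], "' rejected: ambiguity or non-nucleotide ",
              "characters", call. = FALSE)
      next
    }
    if (nchar(s) == 0L || nchar(s) %% 3L != 0L) {
      warning("record '", ids[i], "' rejected: length ", nchar(s),
              " not a positive multiple of 3", call. = FALSE)
      next
    }
    codons <- split_codons(s)
    n <- length(codons)
    if (is_stop_codon(codons[n])) {
      codons <- codons[-n]
      s <- paste(codons, collapse = "")
      stripped <- c(stripped, ids[i])
      if (length(codons) == 0L) {
        warning("record '", ids[i], "' rejected: empty after stop removal",
                call. = FALSE)
        next
      }
    }
    if (any(is_stop_codon(codons))) {
      warning("record '", ids[i], "' rejected: internal stop codon at codon ",
              which(is_stop_codon(codons))[1L], call. = FALSE)
      next
    }
    seqs[i] <- s
    keep[i] <- TRUE
  }
  out <- data.frame(id = ids[keep], seq = seqs[keep],
                    stringsAsFactors = FALSE)
  attr(out, "stripped_stop") <- stripped
  attr(out, "rejected") <- ids[!keep]
  class(out) <- c("orf_set", "data.frame")
  out
}

#' Write an ORF set to FASTA
#'
#' Sequences are written unwrapped so that `read_orfs(write_orfs(x))` is the
#' identity on accepted records.
#'
#' @param orfs An `orf_set` (or data.frame with `id` and `seq` columns).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_orfs <- function(orfs, path) {
  xs <- Biostrings::BStringSet(setNames(orfs$seq, orfs$id))
  Biostrings::writeXStringSet(xs, path, width = 20001L)
  invisible(path)
}

#' Read a sequence-to-organism-group assignment table
#'
#' Reads a two-column TSV mapping sequence id to organism-group label, as
#' used by the cross-group conservation analysis. A header line is
#' auto-detected: the first row is treated as data if (and only if) its
#' second field recurs as a group label later in the file. Lines starting
#' with `#` are ignored.
#'
#' @param path Path to a TSV file with rows `id<TAB>group`.
#' @param orf_ids Optional character vector of known sequence ids; mapped
#'   ids absent from it trigger a warning (the mapping is kept).
#' @return A `group_table`: data.frame with columns `id` and `group`, plus a
#'   `summary` attribute (per-group sequence counts).
#' @export
read_groups <- function(path, orf_ids = NULL) {
  if (!file.exists(path)) stop("group table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("group table is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop("malformed group-table row at line ", lineno[bad], ": expected 2 ",
         "tab-separated fields, found ", nf[bad], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  ids <- m[, 1L]
  groups <- m[, 2L]
  # header heuristic: first row is data iff its second field repeats below
  if (length(ids) > 1L && !(groups[1L] %in% groups[-1L])) {
    ids <- ids[-1L]
    groups <- groups[-1L]
  }
  if (any(!nzchar(ids)) || any(!nzchar(groups))) {
    stop("empty id or group label in group table", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in group table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(orf_ids)) {
    missing <- setdiff(ids, orf_ids)
    if (length(missing) > 0L) {
      warning(length(missing), " mapped id(s) absent from the ORF set: ",
              paste(head(missing, 5L), collapse = ", "),
              if (length(missing) > 5L) ", ..." else "", call. = FALSE)
    }
  }
  out <- data.frame(id = ids, group = groups, stringsAsFactors = FALSE)
  attr(out, "summary") <- table(groups)
  class(out) <- c("group_table", "data.frame")
  out
}

#' @export
print.group_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat("group_table:", nrow(x), "sequences in", length(s), "groups\n")
  for (g in names(s)) cat("  ", g, ": ", s[[g]], "\n", sep = "")
  invisible(x)
}

#' Write a data.frame as TSV with a commented header line
#'
#' All pipeline output tables share this format: a single header line
#' starting with `#`, then tab-separated rows.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
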