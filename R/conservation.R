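#' Residue-identity conservation component of a column
#'
#' Maps an amino-acid alignment column to \eqn{c \in [0,1]} via
#' `c = (m - 1) / (n - 1)`, with `m` the modal residue count and `n` the
#' number of non-gap residues: `c = 1` exactly when the residue is 100%
#' conserved and `c = 0` exactly when all residues are distinct.
#'
#' @param column Character vector of one-letter residues and `"-"` gaps.
#' @return A number in \eqn{[0,1]}, or `NA` when fewer than 2 non-gap
#'   residues are present (position unscored).
#' @export
conservation_component <- function(column) {
  res <- column[column != "-" & !is.na(column)]
  n <- length(res)
  if (n < 2L) return(NA_real_)
  m <- max(table(res))
  (m - 1) / (n - 1)
}

#' Selection component from a standardized dN-dS z-score
#'
#' Maps the per-site z (sign convention: positive = purifying) to
#' \eqn{p \in [0,1]} by `p = clamp(z / 2, 0, 1)`: `p = 1` exactly at z >= 2
#' ("more than 2 SDs above the mean" selection), `p = 0` at z <= 0 (at or
#' below the gene mean), linear in between. Unscored positions (`NA` z)
#' get `p = 0`, the conservative choice.
#'
#' @param z Numeric vector of z-scores (may contain `NA`).
#' @return Numeric vector in \eqn{[0,1]}.
#' @export
selection_component <- function(z) {
  p <- pmin(pmax(z / 2, 0), 1)
  p[is.na(p)] <- 0
  p
}

#' Combined 0-2 per-site conservation score
#'
#' Adds the residue-identity component and the selection component:
#' `score = c + p` in \eqn{[0,2]}. A score of 2 at a site means both 100%
#' residue identity and selection more than 2 SDs above the gene mean; a
#' score of 0 means no residue conservation and at-or-below-mean selective
#' pressure.
#'
#' @param aln A `codon_alignment` (used for the amino-acid columns).
#' @param sel A `site_selection_profile` for the same alignment, or `NULL`
#'   to compute one with defaults.
#' @param low_support_gap_frac Positions with more than this fraction of
#'   gaps are flagged `low_support`.
#' @param min_pairs Passed to [site_selection_profile()] when `sel` is NULL.
#' @param categorical If `TRUE`, report the discrete \{0, 1, 2\} version of
#'   the score instead of the continuous one: one point for 100% residue
#'   identity, one point for z >= 2.
#' @return A `conservation_profile`: data.frame with columns `position`,
#'   `modal_freq`, `c`, `z`, `p`, `score`, `low_support`.
#' @export
site_scores <- function(aln, sel = NULL, low_support_gap_frac = 0.5,
                        min_pairs = 3L, categorical = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(sel)) sel <- site_selection_profile(aln, min_pairs = min_pairs)
  aamat <- alignment_aa_matrix(aln)
  if (nrow(sel) != ncol(aamat) ||
      !identical(sel$position, aln$aa_start:aln$aa_end)) {
    stop("selection profile does not index the same reference positions ",
         "as the alignment", call. = FALSE)
  }
  npos <- ncol(aamat)
  cvec <- modal <- rep(NA_real_, npos)
  gapfrac <- numeric(npos)
  for (i in seq_len(npos)) {
    col <- aamat[, i]
    res <- col[col != "-"]
    gapfrac[i] <- 1 - length(res) / length(col)
    if (length(res) >= 2L) {
      modal[i] <- max(table(res)) / length(res)
      cvec[i] <- conservation_component(col)
    }
  }
  p <- selection_component(sel$z)
  if (categorical) {
    cvec <- ifelse(is.na(cvec), NA_real_, as.numeric(cvec == 1))
    p <- as.numeric(!is.na(sel$z) & sel$z >= 2)
  }
  score <- ifelse(is.na(cvec), NA_real_, cvec + p)
  out <- data.frame(position = sel$position, modal_freq = modal,
                    c = cvec, z = sel$z, p = p, score = score,
                    low_support = gapfrac > low_support_gap_frac)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Sliding-window mean conservation scores
#'
#' Means of the per-site score over every full window of `w` consecutive
#' reference positions (step 1, no partial edge windows). Unscored sites
#' inside a window are ignored in the mean; a window with no scored site
#' gets `NA`.
#'
#' @param profile A `conservation_profile`.
#' @param w Window width in codons (default 21).
#' @return Data frame with `start`, `end` (reference numbering, inclusive)
#'   and `window_mean`.
#' @export
window_scores <- function(profile, w = 21L) {
  n <- nrow(profile)
  if (n < w) stop("profile has ", n, " positions, fewer than the window ",
                  "width ", w, call. = FALSE)
  s <- profile$score
  nw <- n - w + 1L
  means <- vapply(seq_len(nw), function(i) {
    win <- s[i:(i + w - 1L)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  data.frame(start = profile$position[seq_len(nw)],
             end = profile$position[seq_len(nw)] + w - 1L,
             window_mean = means)
}

#' Top non-overlapping linear-motif windows
#'
#' Greedy extraction of the highest-scoring windows: windows are ranked by
#' mean score (ties broken leftmost), and each selected window suppresses
#' all windows overlapping it. Selection stops after `k` motifs or when no
#' non-overlapping window remains (a message reports early exhaustion).
#'
#' @param windows Output of [window_scores()].
#' @param k Number of motifs to report.
#' @return A `motif_table`: data.frame with `rank`, `start`, `end`,
#'   `window_mean`.
#' @export
top_motifs <- function(windows, k = 2L) {
  stopifnot(k >= 1L)
  avail <- windows[!is.na(windows$window_mean), , drop = FALSE]
  # order: score descending, then leftmost start
  avail <- avail[order(-avail$window_mean, avail$start), , drop = FALSE]
  sel <- list()
  while (length(sel) < k && nrow(avail) > 0L) {
    top <- avail[1L, ]
    sel[[length(sel) + 1L]] <- top
    keep <- avail$end < top$start | avail$start > top$end
    avail <- avail[keep, , drop = FALSE]
  }
  if (length(sel) < k) {
    message("only ", length(sel), " non-overlapping motif window(s) ",
            "available (requested ", k, ")")
  }
  out <- do.call(rbind, sel)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      window_mean = numeric(0))
  }
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  class(out) <- c("motif_table", "data.frame")
  out
}
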