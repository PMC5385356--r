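#' Per-group conservation flags for one alignment column
#'
#' A group counts as conserved at a position when all its non-gap residues
#' are identical and at least `min_group_coverage` of its members are
#' non-gap (a mostly-gapped group cannot count as conserved).
#'
#' @param column Character vector of residues/`"-"`, named or ordered as
#'   `ids`.
#' @param ids Sequence ids, parallel to `column`.
#' @param group_table A `group_table` mapping every id to a group.
#' @param min_group_coverage Minimum non-gap fraction per group.
#' @return Named logical vector, one flag per group.
#' @export
group_conserved <- function(column, ids, group_table,
                            min_group_coverage = 0.5) {
  grp <- group_table$group[match(ids, group_table$id)]
  if (anyNA(grp)) {
    stop("sequence(s) not mapped to any group: ",
         paste(head(ids[is.na(grp)], 5L), collapse = ", "), call. = FALSE)
  }
  vapply(split(column, grp), function(res) {
    nz <- res[res != "-"]
    length(nz) >= 1L &&
      length(nz) / length(res) >= min_group_coverage &&
      length(unique(nz)) == 1L
  }, logical(1))
}

#' Cross-group conservation profile of a protein alignment
#'
#' For every alignment column, computes the per-group conserved flags and
#' the number of groups conserved, then assigns the nested category used in
#' the endospanin-style analysis: `all` (conserved in every group), `ge4`,
#' `ge3`, `ge2` (thresholds G-1, ..., 2 for G groups) or `none`. The
#' exclusive color bands reported alongside are exactly-all, exactly-(G-1),
#' ..., exactly-2.
#'
#' @param aamat Character matrix of aligned residues (rows = sequences,
#'   `"-"` gaps), with rownames as ids, e.g. from [alignment_aa_matrix()].
#' @param group_table A `group_table` covering all rows.
#' @param min_group_coverage Passed to [group_conserved()].
#' @return A `group_conservation_profile`: list with `flags` (positions x
#'   groups logical matrix), `n_groups_conserved`, `category` (factor) and
#'   `G`.
#' @export
group_conservation_profile <- function(aamat, group_table,
                                       min_group_coverage = 0.5) {
  ids <- rownames(aamat)
  if (is.null(ids)) stop("alignment matrix must have row names (ids)",
                         call. = FALSE)
  groups <- sort(unique(group_table$group))
  G <- length(groups)
  npos <- ncol(aamat)
  flags <- matrix(FALSE, npos, G, dimnames = list(NULL, groups))
  for (i in seq_len(npos)) {
    flags[i, ] <- group_conserved(aamat[, i], ids, group_table,
                                  min_group_coverage)[groups]
  }
  ncons <- rowSums(flags)
  cat_of <- function(n) {
    if (G >= 1L && n == G) "all"
    else if (n >= 2L) paste0("ge", n)
    else "none"
  }
  category <- vapply(ncons, cat_of, character(1))
  structure(
    list(flags = flags, n_groups_conserved = ncons,
         category = category, G = G),
    class = "group_conservation_profile"
  )
}

#' Category-band percentage summary
#'
#' Converts a cross-group conservation profile (or raw exact-band counts)
#' into the banded percentage summary: for G groups the exclusive bands
#' are exactly-G ("all"), exactly-(G-1), ..., exactly-2 conserved groups.
#' Percentages are computed over `n_positions` and rounded to one decimal;
#' the "any band" total is reported both as the sum of the rounded band
#' percentages (the convention used in the published accounting) and as
#' the unrounded union percentage.
#'
#' @param profile A `group_conservation_profile`, or a numeric vector of
#'   counts for the bands exactly-G, exactly-(G-1), ..., exactly-2.
#' @param n_positions Total alignment positions the percentages refer to.
#' @return Data frame with `band` (`"all"`, `"eq4"`, ... `"eq2"`), `count`,
#'   `percent`, plus attributes `total_rounded` (sum of rounded percents)
#'   and `total_exact` (unrounded union percent).
#' @export
category_percentages <- function(profile, n_positions) {
  stopifnot(n_positions >= 1L)
  if (inherits(profile, "group_conservation_profile")) {
    G <- profile$G
    if (G < 2L) stop("category bands need at least 2 groups", call. = FALSE)
    counts <- vapply(seq(G, 2L), function(n)
      sum(profile$n_groups_conserved == n), numeric(1))
  } else {
    counts <- as.numeric(profile)
    G <- length(counts) + 1L
  }
  band <- c("all", if (G > 2L) paste0("eq", (G - 1L):2L) else character(0))
  percent <- round(100 * counts / n_positions, 1)
  out <- data.frame(band = band, count = counts, percent = percent)
  attr(out, "total_rounded") <- sum(percent)
  attr(out, "total_exact") <- round(100 * sum(counts) / n_positions, 1)
  out
}
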