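#' Tamura-Nei (TN93) pairwise distance
#'
#' Closed-form TN93 evolutionary distance between two aligned nucleotide
#' rows. Sites where either row carries a gap or a non-ACGT character are
#' excluded pairwise; base frequencies are the empirical frequencies of the
#' two sequences combined over the comparable sites. The model
#' distinguishes purine transitions (A<->G), pyrimidine transitions
#' (C<->T), and transversions.
#'
#' When a logarithm argument is non-positive the pair is saturated and the
#' configured cap is returned with a warning rather than `NaN`, so one
#' divergent pair cannot poison a whole distance matrix.
#'
#' @param a,b Character vectors of single characters (aligned rows of equal
#'   length).
#' @param cap Distance (substitutions/site) returned on saturation.
#' @return Non-negative distance in substitutions per site.
#' @export
tn93_distance <- function(a, b, cap = 5.0) {
  stopifnot(length(a) == length(b))
  ok <- a %in% .nucs & b %in% .nucs
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n == 0L) {
    stop("no comparable (gap-free in both rows) sites", call. = FALSE)
  }
  pi <- (tabulate(match(a, .nucs), 4L) + tabulate(match(b, .nucs), 4L)) /
    (2 * n)
  names(pi) <- .nucs
  diff <- a != b
  p1 <- sum(diff & is_transition(a, b) & a %in% c("A", "G")) / n # purine ts
  p2 <- sum(diff & is_transition(a, b) & a %in% c("C", "T")) / n # pyrimidine ts
  q <- sum(diff & !is_transition(a, b)) / n                      # transversions
  piR <- pi[["A"]] + pi[["G"]]
  piY <- pi[["C"]] + pi[["T"]]
  k1 <- 2 * pi[["A"]] * pi[["G"]]
  k2 <- 2 * pi[["C"]] * pi[["T"]]
  saturate <- function() {
    warning("TN93 saturated; returning cap ", cap, call. = FALSE)
    cap
  }
  if (piR <= 0 || piY <= 0) {
    # degenerate composition: fall back to transversion-only terms
    if (p1 + p2 > 0) return(saturate())
  }
  term <- 0
  if (k1 > 0) {
    w1 <- 1 - piR * p1 / k1 - q / (2 * piR)
    if (w1 <= 0) return(saturate())
    term <- term - (k1 / piR) * log(w1)
  } else if (p1 > 0) {
    return(saturate())
  }
  if (k2 > 0) {
    w2 <- 1 - piY * p2 / k2 - q / (2 * piY)
    if (w2 <= 0) return(saturate())
    term <- term - (k2 / piY) * log(w2)
  } else if (p2 > 0) {
    return(saturate())
  }
  if (piR > 0 && piY > 0) {
    w3 <- 1 - q / (2 * piR * piY)
    if (w3 <= 0) return(saturate())
    c3 <- 2 * (piR * piY - k1 * piY / (2 * piR) - k2 * piR / (2 * piY))
    term <- term - c3 * log(w3)
  } else if (q > 0) {
    return(saturate())
  }
  max(term, 0)
}

#' TN93 distance matrix from an alignment
#'
#' Computes all pairwise TN93 distances on the nucleotide view of a codon
#' alignment (or any character matrix of aligned nucleotides), with
#' pairwise deletion of gapped sites.
#'
#' @param x A `codon_alignment` or a character matrix (rows = sequences).
#' @param cap Saturation cap passed to [tn93_distance()].
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
tn93_matrix <- function(x, cap = 5.0) {
  m <- if (inherits(x, "codon_alignment")) alignment_nuc_matrix(x) else x
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(D)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- tn93_distance(m[i, ], m[j, ], cap = cap)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative estimated branch
#' lengths are clamped to zero and the total clamped deficit reported via a
#' message.
#'
#' @param D Symmetric distance matrix with row/column names, n >= 3.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa",
                         call. = FALSE)
  tree <- ape::nj(D)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative NJ branch length(s); total ",
            "deficit ", format(-sum(tree$edge.length[neg]), digits = 4))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the point-estimate NJ tree from TN93 distances on the codon
#' alignment, then resamples codon columns with replacement `n_reps` times,
#' rebuilds an NJ tree per replicate, and annotates each internal
#' bipartition of the point tree with the percentage of replicates
#' containing it (written as node labels, MEGA-style). Replicates in which
#' a distance is undefined (a pair with zero comparable sites) are dropped;
#' more than 10% dropped is a hard error.
#'
#' @param aln A `codon_alignment`.
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param seed Integer seed for the column resampling.
#' @param cap Saturation cap for TN93.
#' @return A `phylo` tree; `node.label` holds supports in \eqn{[0, 100]}
#'   (the root label is empty), and attribute `n_used` records the number
#'   of successful replicates.
#' @export
bootstrap_supports <- function(aln, n_reps = 500L, seed = 1L, cap = 5.0) {
  stopifnot(n_reps >= 1L)
  codons <- if (inherits(aln, "codon_alignment")) aln$codons else aln
  point <- nj_tree(tn93_matrix(expand_nuc(codons), cap = cap))
  set.seed(seed)
  p <- ncol(codons)
  btrees <- vector("list", n_reps)
  dropped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(p, p, replace = TRUE)
    rep_tree <- tryCatch(
      suppressWarnings(
        nj_tree(tn93_matrix(expand_nuc(codons[, cols, drop = FALSE]),
                            cap = cap))),
      error = function(e) NULL
    )
    if (is.null(rep_tree)) dropped <- dropped + 1L else btrees[[r]] <- rep_tree
  }
  if (dropped > 0.1 * n_reps) {
    stop(dropped, " of ", n_reps, " bootstrap replicates failed (> 10%)",
         call. = FALSE)
  }
  btrees <- btrees[!vapply(btrees, is.null, logical(1))]
  n_used <- length(btrees)
  class(btrees) <- "multiPhylo"
  counts <- ape::prop.clades(point, btrees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- round(100 * counts / n_used, 1)
  labels <- as.character(supports)
  labels[1L] <- ""   # root bipartition of an unrooted tree is trivial
  point$node.label <- labels
  attr(point, "n_used") <- n_used
  attr(point, "dropped") <- dropped
  point
}

# expand a codon character matrix to a nucleotide character matrix
expand_nuc <- function(codons) {
  p <- ncol(codons)
  out <- matrix("-", nrow(codons), 3L * p,
                dimnames = list(rownames(codons), NULL))
  for (k in 1:3) out[, seq(k, 3L * p, by = 3L)] <- substr(codons, k, k)
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D Symmetric matrix with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(formatC(D[i, ], format = "f", digits = 6),
                           collapse = " ")), con)
  }
  invisible(path)
}
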