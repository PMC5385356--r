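#' Expected synonymous and nonsynonymous sites of a codon
#'
#' Nei-Gojobori site counting: for each of the three codon positions, the
#' fraction of the three possible single-nucleotide changes that is
#' synonymous contributes to S, the nonsynonymous fraction to N. Changes
#' creating a stop codon are excluded from both counts (the denominator
#' stays 3 per position, so S + N <= 3, with equality only for codons with
#' no stop neighbors).
#'
#' @param codon A sense codon string.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' ng86_expected_sites("TTT") # S = 1/3, N = 8/3
#' @export
ng86_expected_sites <- function(codon) {
  idx <- codon_index(codon)
  if (is.na(idx)) stop("not a codon: ", codon, call. = FALSE)
  if (codon_aas()[idx] == "*") {
    stop("stop codon has no site counts: ", codon, call. = FALSE)
  }
  tab <- ng86_site_table()
  c(S = tab$S[idx], N = tab$N[idx])
}

# per-codon S and N for all 64 codons (NA at stops), cached
ng86_site_table <- function() {
  if (!is.null(.consmotif_cache$sites)) return(.consmotif_cache$sites)
  codons <- all_codons()
  aas <- codon_aas()
  S <- N <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (aas[i] == "*") next
    s <- n <- 0
    cod <- strsplit(codons[i], "")[[1L]]
    for (pos in 1:3) {
      for (alt in setdiff(.nucs, cod[pos])) {
        mut <- cod
        mut[pos] <- alt
        j <- codon_index(paste(mut, collapse = ""))
        if (aas[j] == "*") next           # stop neighbors excluded
        if (aas[j] == aas[i]) s <- s + 1 / 3 else n <- n + 1 / 3
      }
    }
    S[i] <- s
    N[i] <- n
  }
  .consmotif_cache$sites <- list(S = S, N = N)
  .consmotif_cache$sites
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Counts the synonymous (`sd`) and nonsynonymous (`nd`) single-nucleotide
#' steps separating two sense codons. When the codons differ at k
#' positions, counts are averaged over all k! mutational pathways;
#' pathways passing through a stop codon are excluded. If every pathway is
#' excluded the average falls back to all pathways, stop-passing included
#' (a message is emitted the first time this happens in a session).
#'
#' @param c1,c2 Sense codon strings.
#' @return Named numeric vector `c(sd = ..., nd = ...)`; `sd + nd` equals
#'   the number of differing positions.
#' @export
ng86_pair_counts <- function(c1, c2) {
  i <- codon_index(c1)
  j <- codon_index(c2)
  if (is.na(i) || is.na(j)) stop("not a codon: ", c1, " / ", c2,
                                 call. = FALSE)
  aas <- codon_aas()
  if (aas[i] == "*" || aas[j] == "*") {
    stop("pair counts undefined for stop codons", call. = FALSE)
  }
  tab <- ng86_pair_table()
  c(sd = tab$SD[i, j], nd = tab$ND[i, j])
}

# 64x64 sd/nd tables by pathway enumeration, cached
ng86_pair_table <- function() {
  if (!is.null(.consmotif_cache$pairs)) return(.consmotif_cache$pairs)
  codons <- all_codons()
  aas <- codon_aas()
  SD <- ND <- matrix(NA_real_, 64L, 64L)
  perms <- list(
    `1` = matrix(1L, 1L, 1L),
    `2` = rbind(c(1L, 2L), c(2L, 1L)),
    `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  chars <- strsplit(codons, "")
  fallback_used <- FALSE
  for (i in seq_len(64L)) {
    if (aas[i] == "*") next
    for (j in seq_len(64L)) {
      if (aas[j] == "*") next
      if (i == j) {
        SD[i, j] <- ND[i, j] <- 0
        next
      }
      from <- chars[[i]]
      to <- chars[[j]]
      dpos <- which(from != to)
      k <- length(dpos)
      pm <- perms[[as.character(k)]]
      path_sd <- path_nd <- numeric(nrow(pm))
      valid <- logical(nrow(pm))
      for (p in seq_len(nrow(pm))) {
        cur <- from
        s <- n <- 0
        ok <- TRUE
        for (step in dpos[pm[p, ]]) {
          prev_aa <- aas[codon_index(paste(cur, collapse = ""))]
          cur[step] <- to[step]
          nxt <- codon_index(paste(cur, collapse = ""))
          nxt_aa <- aas[nxt]
          if (nxt_aa == "*") ok <- FALSE
          if (nxt_aa == prev_aa) s <- s + 1 else n <- n + 1
        }
        path_sd[p] <- s
        path_nd[p] <- n
        valid[p] <- ok
      }
      if (any(valid)) {
        SD[i, j] <- mean(path_sd[valid])
        ND[i, j] <- mean(path_nd[valid])
      } else {
        fallback_used <- TRUE
        SD[i, j] <- mean(path_sd)
        ND[i, j] <- mean(path_nd)
      }
    }
  }
  if (fallback_used) {
    message("some codon pairs have only stop-passing pathways; ",
            "averaged over all pathways for those pairs")
  }
  .consmotif_cache$pairs <- list(SD = SD, ND = ND)
  .consmotif_cache$pairs
}

#' Per-site selection profile of a codon alignment
#'
#' For every reference position, all unordered pairs of non-gap codons are
#' compared: per pair, the nonsynonymous difference proportion
#' `pN = nd / Nbar` and synonymous proportion `pS = sd / Sbar`, where
#' `Nbar`, `Sbar` are the pair-averaged expected site counts. `dN` and
#' `dS` at a position are the means over pairs, `d = dN - dS`, and the
#' z-score standardizes `d` across scored positions with the sign flipped
#' (`z = (mean(d) - d) / sd(d)`) so that strong purifying selection gives
#' a large positive z. Positions with fewer than `min_pairs` comparable
#' pairs are left unscored (`NA`).
#'
#' No multiple-hit correction is applied: log corrections are unstable on
#' 3-nt windows, so raw proportions are used.
#'
#' @param aln A `codon_alignment` with at least 2 rows.
#' @param min_pairs Minimum comparable pairs for a position to be scored.
#' @return A `site_selection_profile`: data.frame with columns `position`
#'   (reference numbering), `n_pairs`, `dN`, `dS`, `d`, `z`.
#' @export
site_selection_profile <- function(aln, min_pairs = 3L) {
  stopifnot(inherits(aln, "codon_alignment"))
  m <- aln$codons
  if (nrow(m) < 2L) stop("selection profile needs at least 2 sequences",
                         call. = FALSE)
  sites <- ng86_site_table()
  pairs <- ng86_pair_table()
  npos <- ncol(m)
  positions <- aln$aa_start:aln$aa_end
  n_pairs <- integer(npos)
  dN <- dS <- rep(NA_real_, npos)
  idx_all <- matrix(codon_index(m), nrow(m), npos)
  for (pcol in seq_len(npos)) {
    v <- idx_all[, pcol]
    v <- v[!is.na(v)]
    np <- length(v) * (length(v) - 1L) / 2L
    n_pairs[pcol] <- np
    if (np < min_pairs) next
    cb <- combn(length(v), 2L)
    a <- v[cb[1L, ]]
    b <- v[cb[2L, ]]
    nd <- pairs$ND[cbind(a, b)]
    sdd <- pairs$SD[cbind(a, b)]
    nbar <- (sites$N[a] + sites$N[b]) / 2
    sbar <- (sites$S[a] + sites$S[b]) / 2
    pN <- ifelse(nd == 0, 0, nd / nbar)
    pS <- ifelse(sdd == 0, 0, sdd / sbar)
    dN[pcol] <- mean(pN)
    dS[pcol] <- mean(pS)
  }
  d <- dN - dS
  scored <- !is.na(d)
  z <- rep(NA_real_, npos)
  if (sum(scored) >= 2L) {
    mu <- mean(d[scored])
    sdev <- sd(d[scored])
    z[scored] <- if (sdev > 0) (mu - d[scored]) / sdev else 0
  } else if (sum(scored) == 1L) {
    z[scored] <- 0
  }
  out <- data.frame(position = positions, n_pairs = n_pairs,
                    dN = dN, dS = dS, d = d, z = z)
  class(out) <- c("site_selection_profile", "data.frame")
  out
}
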