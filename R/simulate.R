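#' Simulation configuration for the codon-evolution generator
#'
#' Bundles and validates the parameters of [simulate_alignment()]. The
#' defaults describe the validation condition used throughout: 24 taxa,
#' 200 codons, total tree length 2 expected neutral substitutions per
#' nucleotide site, transition/transversion rate ratio kappa = 2, neutral
#' background (omega = 1) and one planted 21-codon invariant motif under
#' near-complete constraint (omega = 0.02 with the synonymous rate scaled
#' by 0.1, so motif columns are near-identical at both codon and residue
#' level).
#'
#' @param n_taxa Number of leaves.
#' @param n_codons Codons per sequence.
#' @param tree_shape `"balanced"` or `"coalescent"`.
#' @param tree_length Sum of branch lengths, in expected neutral
#'   substitutions per nucleotide site (the unit TN93 distances are
#'   estimated in, so simulated and estimated branch lengths are directly
#'   comparable).
#' @param kappa Transition/transversion rate ratio.
#' @param omega_background Nonsynonymous/synonymous rate ratio outside
#'   motifs.
#' @param motif_intervals List of `c(start, end)` codon intervals (1-based,
#'   inclusive) planted as constrained motifs; may be empty. The default
#'   (`NULL`) plants one centered 21-codon block when the sequence is at
#'   least three windows long (90..110 at the default 200 codons), and
#'   nothing otherwise.
#' @param motif_omega Omega inside motif intervals.
#' @param motif_syn_scale Multiplier on the synonymous rate inside motifs.
#' @param n_groups Number of organism groups to label (assigned by clade:
#'   contiguous blocks in tree tip order), or 0 for no groups.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_taxa = 24L, n_codons = 200L,
                       tree_shape = c("balanced", "coalescent"),
                       tree_length = 2, kappa = 2,
                       omega_background = 1,
                       motif_intervals = NULL,
                       motif_omega = 0.02, motif_syn_scale = 0.1,
                       n_groups = 0L, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_taxa >= 2L, n_codons >= 1L)
  if (tree_length < 0) stop("tree_length must be non-negative",
                            call. = FALSE)
  stopifnot(kappa > 0, omega_background >= 0, motif_omega >= 0,
            motif_syn_scale > 0, n_groups >= 0L)
  if (is.null(motif_intervals)) {
    motif_intervals <- if (n_codons >= 63L) {
      start <- (n_codons - 21L) %/% 2L + 1L
      list(c(start, start + 20L))
    } else {
      list()
    }
  }
  for (iv in motif_intervals) {
    if (length(iv) != 2L || iv[1L] > iv[2L] || iv[1L] < 1L ||
        iv[2L] > n_codons) {
      stop("motif interval out of range [1, ", n_codons, "]: ",
           paste(iv, collapse = ".."), call. = FALSE)
    }
  }
  structure(list(n_taxa = as.integer(n_taxa), n_codons = as.integer(n_codons),
                 tree_shape = tree_shape, tree_length = tree_length,
                 kappa = kappa, omega_background = omega_background,
                 motif_intervals = motif_intervals, motif_omega = motif_omega,
                 motif_syn_scale = motif_syn_scale,
                 n_groups = as.integer(n_groups), seed = as.integer(seed)),
            class = "sim_config")
}

# balanced topology over n leaves by recursive halving (newick, no lengths)
balanced_newick <- function(n, offset = 0L) {
  if (n == 1L) return(paste0("L", offset + 1L))
  h <- n %/% 2L
  paste0("(", balanced_newick(h, offset), ",",
         balanced_newick(n - h, offset + h), ")")
}

# per-codon jump structure under the kappa-weighted neighbor model, cached:
# for each sense codon, its sense single-nucleotide neighbors, the kappa
# factor of each move and whether it is synonymous; plus the normalizer
# making mean neutral total rate 1 over a uniform sense-codon distribution
codon_jump_table <- function(kappa) {
  key <- paste0("jump_", format(kappa, digits = 12))
  if (!is.null(.consmotif_cache[[key]])) return(.consmotif_cache[[key]])
  codons <- all_codons()
  aas <- codon_aas()
  tab <- vector("list", 64L)
  for (i in seq_len(64L)) {
    if (aas[i] == "*") next
    cod <- strsplit(codons[i], "")[[1L]]
    nb <- integer(0)
    fac <- numeric(0)
    syn <- logical(0)
    for (pos in 1:3) {
      for (alt in setdiff(.nucs, cod[pos])) {
        mut <- cod
        mut[pos] <- alt
        j <- codon_index(paste(mut, collapse = ""))
        if (aas[j] == "*") next   # stop states forbidden
        nb <- c(nb, j)
        fac <- c(fac, if (is_transition(cod[pos], alt)) kappa else 1)
        syn <- c(syn, aas[j] == aas[i])
      }
    }
    tab[[i]] <- list(nb = nb, fac = fac, syn = syn)
  }
  sense <- which(aas != "*")
  # neutral (omega = 1) mean total jump rate over uniform sense codons
  qbar <- mean(vapply(sense, function(i) sum(tab[[i]]$fac), numeric(1)))
  out <- list(tab = tab, qbar = qbar, sense = sense)
  .consmotif_cache[[key]] <- out
  out
}

# evolve one codon state along one branch (Gillespie jumps); blen is in
# expected neutral substitutions per nucleotide site, the same unit TN93
# distances are estimated in

evolve_site <- function(state, blen, omega, syn_scale, jump) {
  t <- 0
  repeat {
    nbr <- jump$tab[[state]]
    w <- nbr$fac * ifelse(nbr$syn, syn_scale, omega)
    # branch lengths are per nucleotide site; a codon spans 3 sites
    total <- 3 * sum(w) / jump$qbar
    if (total <= 0) return(state)
    t <- t + rexp(1L, total)
    if (t > blen) return(state)
    state <- nbr$nb[sample.int(length(w), 1L, prob = w)]
  }
}

#' Simulate a codon alignment on a tree with site-specific omega
#'
#' Draws a root sequence uniformly over sense codons and evolves it along
#' a tree by exact stochastic simulation: each site independently performs
#' continuous-time single-nucleotide jumps among sense codons, with rate
#' proportional to the kappa transition/transversion factor times omega
#' for nonsynonymous moves (times the motif synonymous-rate scale for
#' synonymous moves inside motifs); stop codons are unreachable. Branch
#' lengths are in expected neutral substitutions per nucleotide site
#' (rates are normalized so a neutral codon site at a uniform sense-codon
#' state makes three jumps per unit length on average, one per nucleotide
#' site). Leaves are emitted ungapped and in frame,
#' so they always pass [read_orfs()]-style validation.
#'
#' @param cfg A [sim_config()].
#' @return A list with `orfs` (an `orf_set`), `truth` (tree as `phylo` and
#'   Newick string, per-site omega, motif intervals, group table or NULL)
#'   and `config`.
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_taxa
  tree <- if (cfg$tree_shape == "balanced") {
    t0 <- ape::read.tree(text = paste0(balanced_newick(n), ";"))
    t0$edge.length <- rep(1, nrow(t0$edge))
    t0
  } else {
    ape::rcoal(n)
  }
  tree$edge.length <- tree$edge.length * cfg$tree_length /
    sum(tree$edge.length)
  tree$tip.label <- sprintf("t%02d", seq_len(n))

  omega <- rep(cfg$omega_background, cfg$n_codons)
  syn_scale <- rep(1, cfg$n_codons)
  for (iv in cfg$motif_intervals) {
    omega[iv[1L]:iv[2L]] <- cfg$motif_omega
    syn_scale[iv[1L]:iv[2L]] <- cfg$motif_syn_scale
  }
  jump <- codon_jump_table(cfg$kappa)

  root_state <- sample(jump$sense, cfg$n_codons, replace = TRUE)
  nnode <- n + tree$Nnode
  states <- matrix(NA_integer_, nnode, cfg$n_codons)
  root <- n + 1L
  states[root, ] <- root_state
  # preorder over edges: parents always precede children in ape's default
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]
    child <- edges[e, 2L]
    st <- states[par, ]
    for (s in seq_len(cfg$n_codons)) {
      st[s] <- evolve_site(st[s], elen[e], omega[s], syn_scale[s], jump)
    }
    states[child, ] <- st
  }
  codons <- all_codons()
  seqs <- vapply(seq_len(n), function(i)
    paste(codons[states[i, ]], collapse = ""), character(1))
  orfs <- orf_set(tree$tip.label, seqs)

  groups <- NULL
  if (cfg$n_groups > 0L) {
    # clade-style blocks in tip order
    cut <- ceiling(seq_along(tree$tip.label) * cfg$n_groups / n)
    groups <- data.frame(id = tree$tip.label,
                         group = paste0("G", cut),
                         stringsAsFactors = FALSE)
    attr(groups, "summary") <- table(groups$group)
    class(groups) <- c("group_table", "data.frame")
  }
  list(orfs = orfs,
       truth = list(tree = tree, newick = ape::write.tree(tree),
                    omega = omega, motif_intervals = cfg$motif_intervals,
                    groups = groups),
       config = cfg)
}

# Jaccard overlap of two integer intervals c(start, end)
interval_jaccard <- function(a, b) {
  inter <- max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L)
  union <- (a[2L] - a[1L] + 1L) + (b[2L] - b[1L] + 1L) - inter
  inter / union
}

#' Motif-recovery experiment over simulated replicates
#'
#' Runs the full discovery pipeline (simulate, star-align on the first
#' taxon, per-site selection, 0-2 conservation score, sliding windows, top
#' motif) on `n_reps` independently seeded replicates of `cfg`, and
#' reports the fraction of replicates whose rank-1 motif window overlaps a
#' planted interval at Jaccard >= `jaccard_min`, together with the mean
#' per-site score inside versus outside the planted intervals. A pipeline
#' failure inside a replicate is recorded as a failed replicate, never
#' silently dropped.
#'
#' @param cfg A [sim_config()] with at least one planted motif.
#' @param n_reps Number of replicates.
#' @param w Window width (default 21).
#' @param jaccard_min Overlap threshold counting as a recovery.
#' @param min_pairs Passed to [site_selection_profile()].
#' @return A list with `recovered` (logical per replicate), `fraction`,
#'   `mean_score_inside`, `mean_score_outside`, `errors` (character per
#'   failed replicate).
#' @export
recovery_experiment <- function(cfg, n_reps = 50L, w = 21L,
                                jaccard_min = 0.5, min_pairs = 3L) {
  if (length(cfg$motif_intervals) == 0L) {
    stop("recovery experiment needs at least one planted motif",
         call. = FALSE)
  }
  recovered <- logical(n_reps)
  inside <- outside <- numeric(n_reps)
  errors <- rep(NA_character_, n_reps)
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r - 1L
      sim <- simulate_alignment(cfg_r)
      aln <- build_reference_alignment(sim$orfs, sim$orfs$id[1L])
      prof <- site_scores(aln, min_pairs = min_pairs)
      top <- top_motifs(window_scores(prof, w = w), k = 1L)
      in_motif <- rep(FALSE, nrow(prof))
      for (iv in cfg$motif_intervals) in_motif[iv[1L]:iv[2L]] <- TRUE
      hit <- any(vapply(cfg$motif_intervals, function(iv)
        interval_jaccard(c(top$start, top$end), iv) >= jaccard_min,
        logical(1)))
      list(hit = hit,
           inside = mean(prof$score[in_motif], na.rm = TRUE),
           outside = mean(prof$score[!in_motif], na.rm = TRUE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[r] <- conditionMessage(res)
      recovered[r] <- FALSE
      inside[r] <- outside[r] <- NA_real_
    } else {
      recovered[r] <- res$hit
      inside[r] <- res$inside
      outside[r] <- res$outside
    }
  }
  list(recovered = recovered, fraction = mean(recovered),
       mean_score_inside = mean(inside, na.rm = TRUE),
       mean_score_outside = mean(outside, na.rm = TRUE),
       errors = errors[!is.na(errors)])
}
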