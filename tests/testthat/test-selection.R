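# independent oracle helpers (deliberately different code path from the
# package: direct enumeration with Biostrings translation, recursive
# pathway expansion)

GC <- Biostrings::GENETIC_CODE
SENSE <- names(GC)[GC != "*"]

oracle_sites <- function(codon) {
  s <- n <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (GC[[mut]] == "*") next
      if (GC[[mut]] == GC[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(S = s, N = n)
}

# recursive enumeration of every mutational pathway between two codons
oracle_paths <- function(from, to) {
  dpos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  walk <- function(cur, remaining, sd, nd, stopped) {
    if (length(remaining) == 0) {
      return(list(list(sd = sd, nd = nd, stopped = stopped)))
    }
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      syn <- GC[[nxt]] == GC[[cur]]
      out <- c(out, walk(nxt, setdiff(remaining, p),
                         sd + syn, nd + !syn,
                         stopped || GC[[nxt]] == "*"))
    }
    out
  }
  paths <- walk(from, dpos, 0, 0, FALSE)
  ok <- !vapply(paths, `[[`, logical(1), "stopped")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

test_that("expected site counts match hand-derived values and bounds", {
  expect_equal(ng86_expected_sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_equal(ng86_expected_sites("ATG"), c(S = 0, N = 3))
  expect_error(ng86_expected_sites("TAA"), "stop")
  for (cod in SENSE) {
    sn <- ng86_expected_sites(cod)
    expect_equal(unname(sn), unname(oracle_sites(cod)), tolerance = 1e-12)
    expect_lte(sum(sn), 3 + 1e-12)
  }
})

test_that("pair counts match definitions for 0- and 1-step pairs", {
  expect_equal(ng86_pair_counts("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(ng86_pair_counts("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(ng86_pair_counts("TTT", "TTA"), c(sd = 0, nd = 1))
  expect_error(ng86_pair_counts("TGA", "TGG"), "stop")
})

test_that("multi-step pair counts average over enumerated pathways", {
  set.seed(8)
  cases <- cbind(sample(SENSE, 40, replace = TRUE),
                 sample(SENSE, 40, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    got <- ng86_pair_counts(cases[i, 1], cases[i, 2])
    want <- oracle_paths(cases[i, 1], cases[i, 2])
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
  # sd + nd equals the number of differing positions
  for (i in seq_len(nrow(cases))) {
    k <- sum(strsplit(cases[i, 1], "")[[1]] != strsplit(cases[i, 2], "")[[1]])
    expect_equal(sum(ng86_pair_counts(cases[i, 1], cases[i, 2])), k)
  }
})

test_that("invariant columns have dN = dS = d = 0", {
  m <- matrix(rep(c("AAA", "TGG", "CCC"), each = 4), nrow = 4)
  rownames(m) <- paste0("s", 1:4)
  colnames(m) <- 1:3
  prof <- site_selection_profile(manual_alignment(m))
  expect_equal(prof$dN, rep(0, 3))
  expect_equal(prof$dS, rep(0, 3))
  expect_equal(prof$d, rep(0, 3))
})

test_that("purely synonymous columns have d < 0 and z above the mean", {
  # col 1: third-position synonymous changes only; col 2: nonsynonymous;
  # col 3: invariant (reference point for z ordering)
  m <- cbind(c("TTT", "TTC", "TTT", "TTC"),
             c("AAA", "GAA", "CAA", "GAA"),
             rep("ATG", 4))
  rownames(m) <- paste0("s", 1:4)
  colnames(m) <- 1:3
  prof <- site_selection_profile(manual_alignment(m))
  expect_equal(prof$dN[1], 0)
  expect_gt(prof$dS[1], 0)
  expect_lt(prof$d[1], 0)
  expect_gt(prof$z[1], 0)          # purifying site scores above the mean
  expect_gt(prof$d[2], 0)
  expect_lt(prof$z[2], 0)
})

test_that("per-site profile equals a brute-force pair tally", {
  set.seed(13)
  ncod <- 12
  m <- t(vapply(1:5, function(i)
    substring(random_orf_seq(ncod), seq(1, ncod * 3, 3), seq(3, ncod * 3, 3)),
    character(ncod)))
  rownames(m) <- paste0("s", 1:5)
  colnames(m) <- seq_len(ncod)
  prof <- site_selection_profile(manual_alignment(m), min_pairs = 1)
  for (j in seq_len(ncod)) {
    pn <- ps <- c()
    for (a in 1:4) for (b in (a + 1):5) {
      cnt <- oracle_paths(m[a, j], m[b, j])
      sa <- oracle_sites(m[a, j])
      sb <- oracle_sites(m[b, j])
      nbar <- (sa[["N"]] + sb[["N"]]) / 2
      sbar <- (sa[["S"]] + sb[["S"]]) / 2
      pn <- c(pn, if (cnt[["nd"]] == 0) 0 else cnt[["nd"]] / nbar)
      ps <- c(ps, if (cnt[["sd"]] == 0) 0 else cnt[["sd"]] / sbar)
    }
    expect_equal(prof$dN[j], mean(pn), tolerance = 1e-12)
    expect_equal(prof$dS[j], mean(ps), tolerance = 1e-12)
  }
})

test_that("profile is invariant to row order and z standardizes to (0, 1)", {
  set.seed(19)
  cfg <- sim_config(n_taxa = 8, n_codons = 40, seed = 23)
  sim <- simulate_alignment(cfg)
  aln <- build_reference_alignment(sim$orfs, sim$orfs$id[1])
  prof <- site_selection_profile(aln)
  aln2 <- aln
  perm <- sample(nrow(aln$codons))
  aln2$codons <- aln$codons[perm, ]
  prof2 <- site_selection_profile(aln2)
  expect_equal(prof2$d, prof$d)
  scored <- !is.na(prof$z)
  expect_equal(mean(prof$z[scored]), 0, tolerance = 1e-10)
  expect_equal(sd(prof$z[scored]), 1, tolerance = 1e-10)
})

test_that("positions under min_pairs are flagged unscored", {
  m <- cbind(c("AAA", "AAG", "---", "---"), rep("TGG", 4))
  rownames(m) <- paste0("s", 1:4)
  colnames(m) <- 1:2
  prof <- site_selection_profile(manual_alignment(m), min_pairs = 3)
  expect_equal(prof$n_pairs, c(1L, 6L))
  expect_true(is.na(prof$d[1]))
  expect_false(is.na(prof$d[2]))
  m1 <- m[1, , drop = FALSE]
  expect_error(site_selection_profile(manual_alignment(m1)), "2 sequences")
})
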