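nuc_sample <- function(n, seed, prob = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(seed)
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)
}

test_that("TN93 is zero on identical rows and symmetric", {
  a <- nuc_sample(300, 1)
  expect_equal(tn93_distance(a, a), 0)
  for (s in 2:4) {
    b <- a
    idx <- sample(300, 40)
    b[idx] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    expect_equal(tn93_distance(a, b), tn93_distance(b, a))
  }
})

test_that("TN93 matches the independent dist.dna implementation", {
  set.seed(12)
  for (rep in 1:5) {
    a <- nuc_sample(600, rep + 100, prob = c(0.35, 0.2, 0.25, 0.2))
    b <- a
    idx <- sample(600, 80)
    b[idx] <- sample(c("A", "C", "G", "T"), 80, replace = TRUE)
    m <- rbind(a = a, b = b)
    ours <- tn93_distance(a, b)
    apes <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                                     pairwise.deletion = TRUE))
    expect_equal(ours, apes, tolerance = 1e-12)
  }
})

test_that("gapped sites are excluded pairwise and all-gap pairs error", {
  a <- c("A", "A", "-", "C", "G", "T")
  b <- c("A", "G", "C", "-", "G", "T")
  # comparable sites: 1,2,5,6 -> one A<->G transition out of 4
  a4 <- a[c(1, 2, 5, 6)]
  b4 <- b[c(1, 2, 5, 6)]
  expect_equal(tn93_distance(a, b), tn93_distance(a4, b4))
  expect_error(tn93_distance(c("-", "A"), c("C", "-")), "comparable")
})

test_that("saturated pairs return the cap with a warning", {
  a <- rep(c("A", "C", "G", "T"), 25)
  b <- rep(c("C", "A", "T", "G"), 25)   # 100% transversions
  expect_warning(d <- tn93_distance(a, b), "saturated")
  expect_equal(d, 5.0)
  expect_warning(d2 <- tn93_distance(a, b, cap = 9), "saturated")
  expect_equal(d2, 9)
})

# construct a pair with exact substitution counts and uniform joint
# composition: n/4 of each base in a, changes applied in frequency-balanced
# swapped pairs so the combined empirical frequencies stay uniform
balanced_pair <- function(n, ts_pur, ts_pyr, tv) {
  stopifnot(n %% 4 == 0)
  a <- rep(c("A", "G", "C", "T"), each = n / 4)
  b <- a
  free <- split(seq_len(n), a)
  take <- function(base, k) {
    if (k == 0) return(integer(0))
    idx <- free[[base]][seq_len(k)]
    free[[base]] <<- free[[base]][-seq_len(k)]
    idx
  }
  b[take("A", ts_pur / 2)] <- "G"
  b[take("G", ts_pur / 2)] <- "A"
  b[take("C", ts_pyr / 2)] <- "T"
  b[take("T", ts_pyr / 2)] <- "C"
  # transversions as one balanced swap pair so composition stays uniform
  b[take("A", tv / 2)] <- "C"
  b[take("C", tv / 2)] <- "A"
  list(a = a, b = b)
}

test_that("TN93 reduces to K2P and JC69 in the corresponding limits", {
  n <- 1200
  # equal base frequencies, equal transition rates -> K2P
  p <- balanced_pair(n, ts_pur = 30, ts_pyr = 30, tv = 40)
  P <- 60 / n
  Q <- 40 / n
  k2p <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(tn93_distance(p$a, p$b), k2p, tolerance = 1e-9)
  # transitions at the 1:2 ratio a uniform process expects -> JC69
  p2 <- balanced_pair(n, ts_pur = 12, ts_pyr = 12, tv = 48)
  pdiff <- 72 / n
  jc <- -0.75 * log(1 - 4 / 3 * pdiff)
  expect_equal(tn93_distance(p2$a, p2$b), jc, tolerance = 1e-9)
})

test_that("a 600-nt transversion-only pair matches the closed form", {
  p <- balanced_pair(600, ts_pur = 0, ts_pyr = 0, tv = 30)
  Q <- 30 / 600
  expected <- -0.5 * log(1 - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(tn93_distance(p$a, p$b), expected, tolerance = 1e-9)
})

test_that("NJ solves the 3-taxon case in closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(D)
  pend <- setNames(tree$edge.length[tree$edge[, 2] <= 3],
                   tree$tip.label[tree$edge[tree$edge[, 2] <= 3, 2]])
  expect_equal(pend[["A"]], 1)
  expect_equal(pend[["B"]], 1)
  expect_equal(pend[["C"]], 3)
})

test_that("NJ recovers additive distances exactly", {
  set.seed(77)
  for (rep in 1:10) {
    true <- ape::rtree(6)
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    D2 <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(D2, D, tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("bootstrap supports are deterministic given the seed and capped", {
  s1 <- random_orf_seq(60, seed = 50)
  set.seed(51)
  mut <- function(s, k) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    pos <- sample(length(cod), k)
    cod[pos] <- vapply(seq_len(k), function(i) random_orf_seq(1), character(1))
    paste(cod, collapse = "")
  }
  orfs <- orf_set(paste0("s", 1:5),
                  c(s1, mut(s1, 6), mut(s1, 6), mut(s1, 18), mut(s1, 18)))
  aln <- build_reference_alignment(orfs, "s1")
  t1 <- bootstrap_supports(aln, n_reps = 50, seed = 99)
  t2 <- bootstrap_supports(aln, n_reps = 50, seed = 99)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("two identical clades get 100 support for the separating split", {
  a <- random_orf_seq(100, seed = 61)
  b <- local({
    cod <- substring(a, seq(1, 300, 3), seq(3, 300, 3))
    set.seed(62)
    pos <- sample(100, 30)
    cod[pos] <- vapply(pos, function(i) random_orf_seq(1), character(1))
    paste(cod, collapse = "")
  })
  orfs <- orf_set(c(paste0("a", 1:3), paste0("b", 1:3)), c(rep(a, 3), rep(b, 3)))
  aln <- build_reference_alignment(orfs, "a1")
  tree <- bootstrap_supports(aln, n_reps = 100, seed = 5)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  target <- which(vapply(pp, function(tips) {
    set <- sort(labs[tips])
    identical(set, sort(paste0("a", 1:3))) ||
      identical(set, sort(paste0("b", 1:3)))
  }, logical(1)))
  expect_true(length(target) >= 1)
  sup <- as.numeric(tree$node.label[target])
  expect_true(any(sup == 100))
})
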