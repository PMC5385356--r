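test_that("conservation component hits both endpoints and the formula", {
  expect_equal(conservation_component(strsplit("KKKKK", "")[[1]]), 1)
  expect_equal(conservation_component(strsplit("KRDEQ", "")[[1]]), 0)
  col10 <- c(rep("K", 7), "R", "D", "E")   # modal count 7 of 10
  expect_equal(conservation_component(col10), 6 / 9)
  # gaps are ignored, not counted as residues
  expect_equal(conservation_component(c("K", "K", "-", "-")), 1)
  expect_true(is.na(conservation_component(c("K", "-", "-"))))
})

test_that("selection component is the clamped linear map of z", {
  expect_equal(selection_component(2), 1)
  expect_equal(selection_component(5), 1)
  expect_equal(selection_component(0), 0)
  expect_equal(selection_component(-3), 0)
  expect_equal(selection_component(1), 0.5)
  expect_equal(selection_component(NA_real_), 0)  # unscored -> conservative
})

test_that("score endpoints: 2 iff fully conserved and z >= 2, 0 iff all-distinct and z <= 0", {
  set.seed(31)
  residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:200) {
    n <- sample(3:12, 1)
    col <- sample(residues, n, replace = runif(1) < 0.7)
    z <- runif(1, -4, 4)
    cc <- conservation_component(col)
    score <- cc + selection_component(z)
    expect_equal(score == 2, cc == 1 && z >= 2)
    expect_equal(score == 0, cc == 0 && z <= 0)
  }
})

test_that("score is monotone in modal frequency and in z", {
  # increasing modal count at fixed n
  cols <- lapply(2:9, function(m) c(rep("K", m), sample(c("R", "D", "E", "Q",
                                                          "N", "S", "T", "G"),
                                                        10 - m)))
  cs <- vapply(cols, conservation_component, numeric(1))
  expect_true(all(diff(cs) > 0))
  zs <- seq(-1, 3, by = 0.25)
  expect_true(all(diff(selection_component(zs)) >= 0))
})

test_that("site_scores combines components additively and flags gappy sites", {
  m <- cbind(rep("AAA", 6),                              # invariant
             c("AAA", "AAG", "CGA", "CGG", "GGA", "GGC"),
             c(rep("TGG", 2), rep("---", 4)))            # > 50% gaps
  rownames(m) <- paste0("s", 1:6)
  colnames(m) <- 1:3
  aln <- manual_alignment(m)
  prof <- site_scores(aln, min_pairs = 1)
  expect_equal(prof$score, prof$c + prof$p)
  expect_false(prof$low_support[1])
  expect_true(prof$low_support[3])
  # permuting sequences never changes scores
  aln2 <- aln
  aln2$codons <- m[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(site_scores(aln2, min_pairs = 1)$score, prof$score)
})

test_that("window means cover full windows only, with the stated default", {
  prof <- data.frame(position = 1:30, score = rep(1, 30))
  ws <- window_scores(prof, w = 21)
  expect_equal(nrow(ws), 10L)
  expect_equal(ws$window_mean, rep(1, 10))
  expect_equal(ws$start, 1:10)
  expect_equal(ws$end, 21:30)
  expect_equal(formals(window_scores)$w, 21L)
  expect_error(window_scores(data.frame(position = 1:5, score = 1:5), 21),
               "fewer")
})

test_that("a planted high-score block maximizes the centered window", {
  score <- rep(0, 80)
  score[30:50] <- 2
  prof <- data.frame(position = 1:80, score = score)
  ws <- window_scores(prof, w = 21)
  # brute-force check of every window mean
  brute <- vapply(1:60, function(i) mean(score[i:(i + 20)]), numeric(1))
  expect_equal(ws$window_mean, brute)
  expect_equal(ws$start[which.max(ws$window_mean)], 30)
})

test_that("top_motifs selects greedily without overlap, ties leftmost", {
  score <- rep(0, 80)
  score[30:50] <- 2
  score[1:10] <- 1
  ws <- window_scores(data.frame(position = 1:80, score = score), w = 21)
  tab <- top_motifs(ws, k = 2)
  expect_equal(tab$start[1], 30)
  expect_equal(tab$end[1], 50)
  # motif 2 is the best window not overlapping 30..50
  rest <- ws[ws$end < 30 | ws$start > 50, ]
  expect_equal(tab$window_mean[2], max(rest$window_mean))
  expect_true(tab$end[2] < tab$start[1] || tab$start[2] > tab$end[1])

  flat <- window_scores(data.frame(position = 1:50, score = rep(1, 50)), 21)
  expect_equal(top_motifs(flat, k = 1)$start, 1)  # leftmost on ties

  expect_message(small <- top_motifs(flat, k = 5), "non-overlapping")
  expect_lt(nrow(small), 5)
  expect_true(all(small$end[-nrow(small)] < small$start[-1] |
                    small$start[-nrow(small)] > small$end[-1]))
})

test_that("the categorical score variant is the {0,1,2} endpoint indicator", {
  m <- cbind(rep("AAA", 6),
             c("AAA", "AAG", "CGA", "CGG", "GGA", "GGC"))
  rownames(m) <- paste0("s", 1:6)
  colnames(m) <- 1:2
  aln <- manual_alignment(m)
  sel <- site_selection_profile(aln, min_pairs = 1)
  cont <- site_scores(aln, sel, min_pairs = 1)
  disc <- site_scores(aln, sel, min_pairs = 1, categorical = TRUE)
  expect_true(all(disc$score %in% c(0, 1, 2)))
  expect_equal(disc$score,
               as.numeric(cont$c == 1) + as.numeric(cont$z >= 2))
})
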