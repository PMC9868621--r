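# Quality filtering and two-round greedy clustering.

test_that("identity and coverage behave on identical, mutated and truncated pairs", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(unname(sequence_identity(s, s)["identity"]), 1)
  expect_equal(unname(sequence_identity(s, s)["coverage"]), 1)
  half <- substr(s, 1, 10)
  m <- sequence_identity(s, half)  # truncation: full identity over the span
  expect_equal(unname(m["identity"]), 1)
  expect_equal(unname(m["coverage"]), 1)
  expect_error(sequence_identity("", s), "empty")
})

test_that("identity agrees with the dynamic-programming oracle", {
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- sample(aa, k, TRUE)
    paste(ch, collapse = "")
  }
  for (rep in 1:8) {
    a <- paste(sample(aa, 40, TRUE), collapse = "")
    b <- mutate(a, sample(2:10, 1))   # related pair: span is stable
    got <- sequence_identity(a, b)
    want <- nw_identity(a, b)
    expect_equal(unname(got["identity"]), unname(want["identity"]),
                 tolerance = 0.03)
  }
  # for arbitrary pairs, co-optimal alignments may differ in span, but the
  # optimal match count is unique: check it against the DP table directly
  for (rep in 1:6) {
    a <- paste(sample(aa, 30, TRUE), collapse = "")
    b <- paste(sample(aa, 25, TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = pmhcprofiler:::match_matrix(), type = "global",
      gapOpening = 0, gapExtension = 0)
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    F <- matrix(0, length(A) + 1, length(B) + 1)
    for (i in seq_along(A)) for (j in seq_along(B))
      F[i + 1, j + 1] <- max(F[i, j] + (A[i] == B[j]), F[i, j + 1], F[i + 1, j])
    expect_equal(Biostrings::score(aln), F[length(A) + 1, length(B) + 1])
  }
})

test_that("greedy clustering groups duplicates and splits dissimilar pairs", {
  cs <- greedy_cluster(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"), threshold = 0.8)
  expect_equal(length(cs$clusters), 1)
  # 5/10 identical positions at threshold 0.8: two clusters
  cs2 <- greedy_cluster(c(a = "AAAAAFFFFF", b = "AAAAAYYYYY"), threshold = 0.8)
  expect_equal(length(cs2$clusters), 2)
  expect_error(greedy_cluster(c(a = "", b = "ACD")), "empty")
})

test_that("cluster assignment matches the brute-force oracle on a 20-sequence set", {
  s <- make_sequence_set(n_clusters = 4, members_per_cluster = 5,
                         length = 50, seed = 21)
  cs <- greedy_cluster(s$sequences, threshold = 0.8)
  got <- cluster_membership(cs)
  want <- oracle_greedy_cluster(s$sequences, threshold = 0.8)
  expect_identical(got[sort(names(got))], want[sort(names(want))])
})

test_that("clustering is invariant to input order and exact at threshold 1", {
  s <- make_sequence_set(n_clusters = 3, members_per_cluster = 3,
                         length = 40, seed = 9)
  cs1 <- greedy_cluster(s$sequences, 0.8)
  cs2 <- greedy_cluster(rev(s$sequences), 0.8)
  expect_identical(cluster_membership(cs1)[sort(names(s$sequences))],
                   cluster_membership(cs2)[sort(names(s$sequences))])
  # threshold 1 + full coverage = exact duplicate groups
  dup <- c(x1 = "AAAA", x2 = "AAAA", y1 = "CCCC", z1 = "AAAC")
  cs3 <- greedy_cluster(dup, threshold = 1, min_coverage = 1)
  mem <- cluster_membership(cs3)
  expect_identical(unname(mem["x1"]), unname(mem["x2"]))
  expect_equal(length(cs3$clusters), 3)
})

test_that("resolution and method filters keep only good X-ray records", {
  rec <- complex_records(
    complex_id = c("a", "b", "c"),
    method = c("X-RAY DIFFRACTION", "X-RAY DIFFRACTION", "CRYO-EM"),
    resolution = c(2.4, 2.6, 2.0),
    cdr_sequences = "GGGG", antigen_sequences = "AAAA",
    immunoglobulin_class = "TCR")
  keep <- filter_records(rec)
  expect_identical(keep$complex_id, "a")
})

test_that("two-round clustering merges truncated antigens and splits new targets", {
  para <- paste(rep("ACDEFGHIKL", 3), collapse = "")  # shared paratope
  full_ag <- paste(rep("MNPQRSTVWY", 6), collapse = "")
  trunc_ag <- substr(full_ag, 1, 15)                   # 25% of full length
  other_ag <- paste(rep("KKKKKKKKKK", 6), collapse = "")
  rec <- complex_records(
    complex_id = c("full", "trnc", "othr"),
    method = "X-RAY DIFFRACTION", resolution = c(2.0, 1.8, 2.2),
    cdr_sequences = para,
    antigen_sequences = c(full_ag, trunc_ag, other_ag),
    immunoglobulin_class = "TCRM")
  out <- two_round_representatives(rec)
  # truncated antigen folds into the full-length target; other target splits
  expect_equal(nrow(out$representatives), 2)
  asg <- out$assignments
  expect_identical(asg$antigen_cluster[asg$complex_id == "full"],
                   asg$antigen_cluster[asg$complex_id == "trnc"])
  expect_false(asg$antigen_cluster[asg$complex_id == "othr"] %in%
                 asg$antigen_cluster[asg$complex_id == "full"])
  # representative of the merged pair is the better-resolution record
  expect_true("trnc" %in% out$representatives$complex_id)
})

test_that("planted redundancy in an 8-record set resolves to the hand-computed representatives", {
  paraA <- paste(rep("ACDEFGHIKL", 3), collapse = "")
  paraB <- paste(rep("WWWWYYYYVV", 3), collapse = "")
  agX <- paste(rep("MNPQRSTVWY", 4), collapse = "")
  agY <- paste(rep("DDDDEEEEKK", 4), collapse = "")
  rec <- complex_records(
    complex_id = c("a1", "a2", "a3", "b1", "b2", "c1", "c2", "c3"),
    method = "X-RAY DIFFRACTION",
    resolution = c(2.1, 1.9, 2.3, 2.0, 2.0, 2.4, 1.5, 2.2),
    cdr_sequences = c(paraA, paraA, paraA, paraA, paraA,
                      paraB, paraB, paraB),
    antigen_sequences = c(agX, agX, agX, agY, agY, agX, agX, agY),
    immunoglobulin_class = "TCR")
  out <- two_round_representatives(rec)
  # (paraA, agX) -> a2 (1.9); (paraA, agY) -> b1 (tie 2.0, lexicographic);
  # (paraB, agX) -> c2 (1.5); (paraB, agY) -> c3
  expect_identical(out$representatives$complex_id, c("a2", "b1", "c2", "c3"))
  expect_true(nrow(out$representatives) <= nrow(rec))
})
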