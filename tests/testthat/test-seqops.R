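test_that("global alignment is optimal, deterministic and symmetric in score", {
  a <- global_align(c(x = "ACGT"), c(y = "ACGT"))
  expect_equal(a$score, 4)
  expect_false(any(grepl("-", a$rows, fixed = TRUE)))

  b <- global_align(c(x = "ACGT"), c(y = "AGT"))
  expect_equal(b$score, 1)
  expect_equal(b$score, brute_nw_score("ACGT", "AGT"))
  expect_equal(sum(strsplit(b$rows[2], "")[[1]] == "-"), 1)

  # optimality vs exhaustive enumeration on random tiny pairs, and score
  # symmetry
  set.seed(11)
  for (i in 1:20) {
    s1 <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), TRUE),
                collapse = "")
    expect_equal(global_align(s1, s2)$score, brute_nw_score(s1, s2))
    expect_equal(global_align(s1, s2)$score, global_align(s2, s1)$score)
  }
})

test_that("alignment scores agree with an established aligner", {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  set.seed(12)
  for (i in 1:15) {
    s1 <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
                collapse = "")
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      s1, s2, substitutionMatrix = sm, gapOpening = 0, gapExtension = 2,
      type = "global"))
    expect_equal(global_align(s1, s2)$score, ref)
  }
})

test_that("invalid residues are rejected with id and position", {
  expect_error(global_align(c(ok = "ACGT"), c(bad = "ACXT")),
               "bad.*position 3")
})

test_that("pairwise identity follows the stated gap policies", {
  expect_equal(pairwise_identity(c("ACGT", "ACGT")), 1.0)
  expect_equal(pairwise_identity(c("AC-GT", "ACCGT")), 4 / 5)
  # terminal gap columns are excluded entirely
  expect_equal(pairwise_identity(c("--ACGT", "TTACGT")), 1.0)
  # internal gap run: one column each vs one per run
  expect_equal(pairwise_identity(c("A--CGT", "AAACGT")), 4 / 6)
  expect_equal(pairwise_identity(c("A--CGT", "AAACGT"),
                                 mode = "one-gap-per-run"), 4 / 5)
  # nothing left after terminal-gap exclusion
  expect_error(pairwise_identity(c("A-", "-A")), "no counted columns")
})

test_that("distance matrix equals independent per-pair recomputation", {
  set.seed(13)
  seqs <- stats::setNames(
    vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
      character(1)),
    paste0("s", 1:5))
  dm <- distance_matrix(seqs)
  expect_equal(attr(dm, "n_alignments"), 10)
  expect_true(isSymmetric(unname(dm)))
  expect_equal(unname(diag(dm)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    oracle <- 1 - pairwise_identity(global_align(seqs[i], seqs[j]))
    expect_equal(dm[i, j], oracle)
  }
  dup <- seqs; names(dup)[2] <- "s1"
  expect_error(distance_matrix(dup), "duplicate")
  two <- c(a = "ACGTACGT", b = "ACGTACGT")
  expect_equal(distance_matrix(two)["a", "b"], 0)
})

test_that("center-star MSA propagates gaps and round-trips exactly", {
  same <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  m <- center_star_msa(same)
  expect_false(any(m == "-"))
  expect_equal(degap(m), same)

  # center equals the argmin of distance-matrix row sums
  seqs <- c(a = "ACGTTTTT", b = "ACGTTTAA", c = "ACGTTTTA")
  dm <- distance_matrix(seqs)
  m2 <- center_star_msa(seqs)
  expect_equal(attr(m2, "center"),
               names(which.min(rowSums(dm))))
  expect_equal(degap(m2), seqs)
  expect_gte(ncol(m2), max(nchar(seqs)))

  # indel-bearing synthetic sequences still round-trip
  cfg <- synth_config(n_taxa = 2, members = 4, seq_length = 120,
                      intra_mut = 0.03, inter_div = 0.25, indel_rate = 0.02,
                      seed = 5)
  g <- generate_taxa(cfg)
  m3 <- center_star_msa(g$records)
  expect_equal(degap(m3), g$records)
  expect_gte(ncol(m3), max(nchar(g$records)))
})

test_that("OTU clustering matches a brute-force agglomerative oracle", {
  set.seed(14)
  cfg <- synth_config(n_taxa = 2, members = 3, seq_length = 150,
                      intra_mut = 0.02, inter_div = 0.3, seed = 21)
  seqs <- generate_taxa(cfg)$records
  dm <- distance_matrix(seqs)
  for (linkage in c("average", "furthest", "nearest")) {
    for (thr in c(0.01, 0.03, 0.1, 0.35)) {
      mine <- lapply(cluster_otus(dm, thr, linkage), `[[`, "members")
      oracle <- brute_agglomerate(dm, thr, linkage)
      expect_equal(partition_key(mine), partition_key(oracle),
                   info = paste(linkage, thr))
    }
  }
})

test_that("OTU clustering honors trivial thresholds and partitions input", {
  seqs <- c(a = "ACGTACGTAA", b = "ACGTACGTAA", c = "TTTTACGTCC",
            d = "ACGGACGTAA")
  dm <- distance_matrix(seqs)
  o0 <- cluster_otus(dm, 0)
  expect_equal(sort(vapply(o0, function(x) length(x$members), 1L)),
               c(1L, 1L, 2L))  # a and b are identical
  o1 <- cluster_otus(dm, 1)
  expect_length(o1, 1)
  expect_setequal(o1[[1]]$members, names(seqs))
  # number of OTUs is non-increasing in the threshold
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.5, 1),
                   function(t) length(cluster_otus(dm, t)), 1L)
  expect_true(all(diff(counts) <= 0))
  # partition at every threshold
  for (t in c(0, 0.1, 0.4)) {
    members <- unlist(lapply(cluster_otus(dm, t), `[[`, "members"))
    expect_setequal(members, names(seqs))
    expect_equal(anyDuplicated(members), 0)
  }
})

test_that("representative choice minimizes summed distance with lexicographic ties", {
  dm <- matrix(c(0, .1, .1,
                 .1, 0, .3,
                 .1, .3, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(pick_representative(c("A", "B", "C"), dm), "A")
  expect_equal(pick_representative("B", dm), "B")
  # B and C are symmetric: tie broken to the smaller id
  dm2 <- matrix(c(0, .2, .2,
                  .2, 0, .4,
                  .2, .4, 0), 3, 3,
                dimnames = list(c("Z", "B", "C"), c("Z", "B", "C")))
  expect_equal(pick_representative(c("B", "C"), dm2), "B")
})

test_that("FASTA round trip preserves records", {
  seqs <- c(s1 = "ACGTACGT", s2 = "TTGGCCAA")
  path <- tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
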