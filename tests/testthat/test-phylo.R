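test_that("JC69 distances match the closed form and saturate", {
  # identical rows -> 0
  m0 <- make_msa(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(jc69_distance(m0)["a", "b"], 0)
  # 3 mismatches in 10 comparable columns -> p = 0.3
  m1 <- make_msa(c(a = "AAAAAAAAAA", b = "CCCAAAAAAA"))
  expect_equal(jc69_distance(m1)["a", "b"], -0.75 * log(1 - 0.4 * 1),
               tolerance = 1e-12)
  expect_equal(jc69_distance(m1)["a", "b"], 0.3831192, tolerance = 1e-6)
  # saturation at p >= 0.75 -> ceiling with warning
  m2 <- make_msa(c(a = "AAAAAAAA", b = "CCCCCCAA"))
  expect_warning(d2 <- jc69_distance(m2), "saturated")
  expect_equal(d2["a", "b"], 5)
  expect_equal(suppressWarnings(jc69_distance(m2, ceiling = 9))["a", "b"], 9)
  # gapped columns are excluded pairwise
  m3 <- make_msa(c(a = "AC--ACGT", b = "ACGTACGT"))
  expect_equal(jc69_distance(m3)["a", "b"], 0)
  # no comparable columns -> error
  m4 <- make_msa(c(a = "AC--", b = "--GT"))
  expect_error(jc69_distance(m4), "no comparable columns")
})

test_that("neighbor joining is exact on 3 leaves and hand-built additive trees", {
  dm3 <- matrix(c(0, 3, 4,
                  3, 0, 5,
                  4, 5, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  st <- neighbor_joining(dm3)
  got <- stats::cophenetic(st$tree)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(got, dm3, tolerance = 1e-12)
  # leaf edges are (1, 2, 3): closed form for 3 taxa
  expect_setequal(round(st$tree$edge.length, 9), c(1, 2, 3))

  tr <- ape::read.tree(text = "((A:1,B:2):0.5,C:3,D:4);")
  dm4 <- stats::cophenetic(tr)
  st4 <- neighbor_joining(dm4)
  expect_equal(stats::cophenetic(st4$tree)[rownames(dm4), colnames(dm4)],
               dm4, tolerance = 1e-9)
  expect_error(neighbor_joining(dm4[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers random additive trees exactly and is order-invariant", {
  for (i in 1:10) {
    fx <- random_additive(sample(4:8, 1), seed = 400 + i)
    st <- neighbor_joining(fx$dm)
    got <- stats::cophenetic(st$tree)[rownames(fx$dm), colnames(fx$dm)]
    expect_equal(got, fx$dm, tolerance = 1e-9)
    # independent oracle: ape's own neighbor joining finds the same topology
    ref <- ape::nj(stats::as.dist(fx$dm))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(st$tree),
                                           ape::unroot(ref))), 0)
    # permuting the input label order leaves the tree metric unchanged
    perm <- sample(rownames(fx$dm))
    st2 <- neighbor_joining(fx$dm[perm, perm])
    expect_equal(stats::cophenetic(st2$tree)[rownames(fx$dm), colnames(fx$dm)],
                 fx$dm, tolerance = 1e-9)
  }
})

test_that("bootstrap support is seeded, bounded and sharp for planted signal", {
  # two well-separated clades of 4 leaves each
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  anc1 <- sample(bases, 300, TRUE)
  anc2 <- anc1
  flip <- sample(300, 90)                      # 30% divergence between clades
  anc2[flip] <- vapply(anc2[flip],
                       function(b) sample(setdiff(bases, b), 1), "")
  mut <- function(x, k) { i <- sample(300, k)
    x[i] <- vapply(x[i], function(b) sample(setdiff(bases, b), 1), ""); x }
  seqs <- c(A1 = paste(mut(anc1, 6), collapse = ""),
            A2 = paste(mut(anc1, 6), collapse = ""),
            A3 = paste(mut(anc1, 6), collapse = ""),
            A4 = paste(mut(anc1, 6), collapse = ""),
            B1 = paste(mut(anc2, 6), collapse = ""),
            B2 = paste(mut(anc2, 6), collapse = ""),
            B3 = paste(mut(anc2, 6), collapse = ""),
            B4 = paste(mut(anc2, 6), collapse = ""))
  msa <- make_msa(seqs)
  st <- bootstrap_support(msa, n_reps = 100, seed = 7)
  expect_true(all(st$support >= 0 & st$support <= 100))
  central <- paste(sort(c("B1", "B2", "B3", "B4")), collapse = "|")
  expect_true(central %in% names(st$support))
  expect_gte(st$support[[central]], 95)
  # determinism
  st2 <- bootstrap_support(msa, n_reps = 100, seed = 7)
  expect_identical(st$support, st2$support)
  # single replicate -> supports are 0 or 100
  st1 <- bootstrap_support(msa, n_reps = 1, seed = 3)
  expect_true(all(st1$support %in% c(0, 100)))
  # < 4 leaves: no internal edges
  st3 <- bootstrap_support(msa[1:3, ], n_reps = 5, seed = 1)
  expect_length(st3$support, 0)
})

test_that("stronger clade separation never lowers median central-edge support", {
  bases <- c("A", "C", "G", "T")
  run <- function(div_sites, seed) {
    set.seed(seed)
    anc1 <- sample(bases, 150, TRUE)
    anc2 <- anc1
    flip <- sample(150, div_sites)
    anc2[flip] <- vapply(anc2[flip],
                         function(b) sample(setdiff(bases, b), 1), "")
    mut <- function(x) { i <- sample(150, 10)
      x[i] <- vapply(x[i], function(b) sample(setdiff(bases, b), 1), ""); x }
    seqs <- stats::setNames(
      c(vapply(1:4, function(i) paste(mut(anc1), collapse = ""), ""),
        vapply(1:4, function(i) paste(mut(anc2), collapse = ""), "")),
      c(paste0("A", 1:4), paste0("B", 1:4)))
    st <- bootstrap_support(make_msa(seqs), n_reps = 60, seed = seed)
    key <- paste(paste0("B", 1:4), collapse = "|")
    if (key %in% names(st$support)) st$support[[key]] else 0
  }
  weak <- vapply(1:20, function(s) run(12, 500 + s), numeric(1))
  strong <- vapply(1:20, function(s) run(24, 500 + s), numeric(1))
  expect_gte(stats::median(strong), stats::median(weak))
})

test_that("supported clades are filtered, oriented to the smaller side and ordered", {
  fx <- random_additive(6, seed = 77)
  msa <- NULL
  st <- neighbor_joining(fx$dm)
  bp <- vtaxa:::.bipartitions(st$tree)
  st$support <- stats::setNames(rep(100, length(bp)), names(bp))
  attr(st$support, "bipartitions") <- bp
  all_cl <- supported_clades(st, 50)
  expect_length(all_cl, length(bp))
  expect_true(all(lengths(all_cl) <= 3))          # smaller side of 6 leaves
  expect_true(all(diff(lengths(all_cl)) >= 0))    # smallest first
  st$support[] <- 0
  expect_length(supported_clades(st, 50), 0)
  # mixed supports keep exactly the passing edges
  st$support[] <- c(60, rep(40, length(bp) - 1))
  one <- supported_clades(st, 50)
  expect_length(one, 1)
  key1 <- names(st$support)[1]
  side <- bp[[key1]]
  other <- setdiff(sort(st$tree$tip.label), side)
  expect_setequal(one[[1]], if (length(other) < length(side)) other else side)
  expect_error(supported_clades(neighbor_joining(fx$dm), 50), "not set")
})
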