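# Shared fixtures and small independent oracles used across test files.

# Adjusted Rand index between two labelings (direct formula).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Exhaustive enumeration of all global alignments (oracle for tiny inputs).
brute_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, (if (av[i] == bv[j]) match else mismatch) +
                    rec(i + 1, j + 1))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Greedy agglomerative clustering oracle (recomputes linkage from scratch
# at every step; independent of hclust).
brute_agglomerate <- function(dm, threshold, linkage = "average") {
  clusters <- as.list(sort(rownames(dm)))
  repeat {
    if (length(clusters) < 2) break
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- dm[clusters[[i]], clusters[[j]], drop = FALSE]
        v <- switch(linkage, average = mean(dd), furthest = max(dd),
                    nearest = min(dd))
        if (v < bestd - 1e-12) { bestd <- v; best <- c(i, j) }
      }
    }
    if (bestd > threshold) break
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  clusters
}

partition_key <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","), "")),
        collapse = ";")
}

# Random unrooted tree with positive branch lengths and its additive
# (path-length) distance matrix.
random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_leaves, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  dm <- stats::cophenetic(tr)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = tr, dm = dm)
}

# Character-matrix MSA from equal-length (optionally gapped) strings.
make_msa <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  class(m) <- c("msa", class(m))
  m
}

# vt_assignment built directly from generator truth (the planted taxa ARE
# the VTs) -- lets metadata/occurrence stages be tested independently of
# delimitation.
truth_assignment <- function(truth) {
  vts <- lapply(truth, `[[`, "member_ids")
  names(vts) <- vapply(truth, `[[`, character(1), "taxon_id")
  structure(list(vts = vts,
                 representatives = vapply(vts, `[`, character(1), 1),
                 provenance = NULL, otus = NULL, tree = NULL, config = NULL),
            class = "vt_assignment")
}

truth_membership <- function(truth) {
  unlist(lapply(truth, function(t)
    stats::setNames(rep(t$taxon_id, length(t$member_ids)), t$member_ids)))
}

# Valid metadata data.frame skeleton; fields can be overridden per test.
meta_row <- function(seq_id, host_order = "Poales", functional_group = "grass",
                     ecosystem = "grassland", continent = "Europe",
                     realm = "Palearctic", climate = "warm temperate",
                     location_id = "L01", origin = "root") {
  data.frame(seq_id = seq_id, host_order = host_order,
             functional_group = functional_group, ecosystem = ecosystem,
             continent = continent, realm = realm, climate = climate,
             location_id = location_id, origin = origin,
             stringsAsFactors = FALSE)
}

random_symmetric_dm <- function(n, labels = paste0("u", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

# Independent stress-1 evaluation (isotonic regression written out here so
# it does not share code with the package).
eval_stress1 <- function(points, dm) {
  delta <- as.vector(stats::as.dist(as.matrix(dm)))
  d <- as.vector(stats::dist(points))
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  dhat[ord] <- stats::isoreg(d[ord])$yf
  sqrt(sum((d - dhat)^2) / sum(d^2))
}
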