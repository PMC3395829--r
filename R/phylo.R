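# Corrected distances, neighbor joining, nonparametric bootstrap support
# and supported-clade extraction.  Trees are ape "phylo" objects wrapped in
# a light "support_tree" container that maps internal-edge bipartitions to
# bootstrap support percentages.

#' Jukes-Cantor (JC69) distance matrix from an alignment
#'
#' For every pair of rows, the mismatch proportion p is computed over
#' columns where both rows are ungapped, and corrected as
#' d = -(3/4) * ln(1 - (4/3) p).  Proportions at or beyond the 0.75
#' saturation point are assigned a finite ceiling.
#'
#' @param msa An \code{msa} character matrix (rows = sequences).
#' @param ceiling Distance assigned at saturation (default 5).
#' @param warn Emit a warning when the ceiling is applied (default TRUE).
#' @return Symmetric distance matrix with row ids as dimnames.
#' @export
jc69_distance <- function(msa, ceiling = 5, warn = TRUE) {
  if (nrow(msa) < 2) stop("need at least 2 rows")
  M <- unclass(msa)
  ids <- rownames(M)
  U <- (M != "-") * 1
  comp <- U %*% t(U)
  off <- upper.tri(comp)
  if (any(comp[off] == 0)) {
    bad <- which(comp == 0 & off, arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 ids[bad[1]], ids[bad[2]]))
  }
  eq <- matrix(0, nrow(M), nrow(M))
  for (b in setdiff(unique(as.vector(M)), "-")) {
    Ib <- (M == b) * 1
    eq <- eq + Ib %*% t(Ib)
  }
  p <- 1 - eq / comp
  sat <- p >= 0.75
  d <- p
  d[!sat] <- -0.75 * log(1 - (4 / 3) * p[!sat])
  if (any(sat[off])) {
    if (warn) warning("saturated p >= 0.75; distance set to ceiling")
    d[sat] <- ceiling
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

# Internal: neighbor joining returning a newick string.  Tie-breaking picks
# the candidate pair whose (sorted) smallest-leaf labels are
# lexicographically smallest.  Negative branch lengths are clamped to zero
# with the deficit shifted to the sibling edge.
.nj_newick <- function(dm) {
  labels <- rownames(dm)
  m <- length(labels)
  D <- dm
  nodes <- as.list(labels)          # newick fragment per active cluster
  minleaf <- labels                 # smallest leaf label per active cluster
  fmt <- function(x) sprintf("%.17g", x)
  while (m > 3) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(minleaf[ij[1]], minleaf[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(li),
                        nodes[[j]], fmt(lj))
    new_min <- min(minleaf[i], minleaf[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_node)
    minleaf <- c(minleaf[keep], new_min)
    m <- m - 1
  }
  # final three-way join (closed form)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[1]], fmt(la),
          nodes[[2]], fmt(lb), nodes[[3]], fmt(lc))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Q-criterion.  Negative branch
#' lengths are clamped to zero with the deficit shifted to the sibling edge
#' (Kuhner-Felsenstein convention); ties in Q are broken by the smallest
#' leaf-label pair, so the result is invariant to input label order.
#'
#' @param dm Symmetric distance matrix with >= 3 labels.
#' @return A \code{support_tree}: list with \code{tree} (unrooted ape
#'   \code{phylo}), \code{support} (NULL until bootstrapped) and
#'   \code{n_reps}.
#' @export
neighbor_joining <- function(dm) {
  if (is.null(rownames(dm)) || nrow(dm) < 3)
    stop("neighbor joining needs a labelled matrix with >= 3 taxa")
  phy <- ape::read.tree(text = .nj_newick(dm))
  structure(list(tree = phy, support = NULL, n_reps = 0L),
            class = "support_tree")
}

# Internal: canonical bipartition keys and leaf sets for all internal edges
# of an unrooted phylo (stored rooted at a basal multifurcation).  The
# canonical side is the one NOT containing the alphabetically smallest leaf;
# keys are its sorted labels joined by "|".  Returns list(key = leaf set of
# the canonical side).
.bipartitions <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 4) return(list())
  pp <- ape::prop.part(phy)
  anchor <- min(phy$tip.label)
  out <- list()
  for (i in seq_along(pp)) {
    node <- nt + i
    if (node == nt + 1) next                     # root: trivial split
    tips <- phy$tip.label[pp[[i]]]
    if (length(tips) < 2 || length(tips) > nt - 2) next
    side <- if (anchor %in% tips) setdiff(phy$tip.label, tips) else tips
    side <- sort(side)
    out[[paste(side, collapse = "|")]] <- side
  }
  out
}
# (canonical sides never contain the anchor leaf, so equal-size ties in
# supported_clades resolve away from it deterministically)

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the reference NJ tree from JC69 distances on the full alignment,
#' then resamples alignment columns with replacement \code{n_reps} times,
#' recomputes distances and tree, and counts how often each internal-edge
#' bipartition of the reference tree is recovered.  Support is the recovery
#' percentage.
#'
#' @param msa An \code{msa} character matrix.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @param ceiling Saturation ceiling passed to \code{\link{jc69_distance}}.
#' @return A \code{support_tree} with \code{support}: named numeric vector,
#'   bipartition key -> percentage in [0, 100].  Alignments with fewer than
#'   4 rows have no internal edges and get an empty support vector.
#' @export
bootstrap_support <- function(msa, n_reps = 100, seed = NULL, ceiling = 5) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref_dm <- jc69_distance(msa, ceiling = ceiling, warn = FALSE)
  st <- neighbor_joining(ref_dm)
  bp <- .bipartitions(st$tree)
  counts <- stats::setNames(numeric(length(bp)), names(bp))
  L <- ncol(msa)
  if (length(bp) > 0) {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      keys <- tryCatch({
        bdm <- jc69_distance(msa[, cols, drop = FALSE],
                             ceiling = ceiling, warn = FALSE)
        names(.bipartitions(neighbor_joining(bdm)$tree))
      }, error = function(e) character(0))
      hit <- names(counts) %in% keys
      counts[hit] <- counts[hit] + 1
    }
  }
  st$support <- 100 * counts / n_reps
  st$n_reps <- as.integer(n_reps)
  attr(st$support, "bipartitions") <- bp
  st
}

#' Extract clades meeting a bootstrap support threshold
#'
#' Returns, for every internal edge whose support meets \code{min_support},
#' the smaller side of its bipartition (the side away from the tree's
#' midpoint for a roughly balanced orientation), ordered smallest first.
#'
#' @param st A \code{support_tree} with supports set.
#' @param min_support Support threshold in percent (default 50).
#' @return List of character vectors (leaf id sets), ordered by size; the
#'   corresponding support values are attached as attribute
#'   \code{"support"}.
#' @export
supported_clades <- function(st, min_support = 50) {
  if (!inherits(st, "support_tree") || is.null(st$support))
    stop("supports are not set; run bootstrap_support() first")
  bp <- attr(st$support, "bipartitions")
  keep <- names(st$support)[st$support >= min_support]
  all_tips <- sort(st$tree$tip.label)
  clades <- lapply(keep, function(k) {
    side <- bp[[k]]
    other <- setdiff(all_tips, side)
    if (length(other) < length(side)) side <- sort(other)
    side
  })
  sup <- unname(st$support[keep])
  ord <- order(lengths(clades),
               vapply(clades, function(x) paste(x, collapse = "|"), ""))
  structure(clades[ord], support = sup[ord])
}
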