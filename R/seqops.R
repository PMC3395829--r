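# Pairwise alignment, identity, distance matrices, center-star MSA and
# OTU clustering.  Sequences are represented throughout as a named character
# vector over {A,C,G,T,N}; names are the sequence ids.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate a set of sequence records
#'
#' Checks that sequences form a named character vector over the DNA alphabet
#' \{A,C,G,T,N\} with unique, nonempty ids.  Lowercase input is accepted and
#' upper-cased.
#'
#' @param seqs Named character vector of sequences.
#' @return The validated (upper-cased) named character vector.
#' @export
validate_records <- function(seqs) {
  if (length(seqs) == 0) stop("no sequences supplied")
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("every sequence must have a nonempty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence: ", ids[!nzchar(seqs)][1])
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character in sequence '%s' at position %d",
                 ids[i], bad[i]))
  }
  seqs
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with linear gap scoring (compiled
#' dynamic program).  The score is the optimum under the given
#' match/mismatch/gap scores.  Ties in the traceback are broken
#' deterministically: diagonal is preferred over a gap in the second
#' sequence, which is preferred over a gap in the first.  Characters are
#' compared by equality, so \code{N} matches only \code{N}.
#'
#' @param a,b Single sequences (length-1 character vectors, optionally named).
#' @param match Score for a matching column (default 1).
#' @param mismatch Score for a mismatching column (default -1).
#' @param gap Score for each gapped column (default -2, must be <= 0).
#' @return Object of class \code{pairwise_alignment}: list with \code{rows}
#'   (two gapped strings of equal length), \code{score} and \code{ids}.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ids <- c(if (is.null(names(a))) "a" else names(a),
           if (is.null(names(b))) "b" else names(b))
  seqs <- validate_records(stats::setNames(c(a, b), make.unique(ids)))
  if (gap > 0) stop("gap score must be <= 0")
  res <- .nw_align_pairs(seqs[1], seqs[2], match, mismatch, gap)
  structure(list(
    rows  = c(res$row_a, res$row_b),
    score = res$score,
    ids   = ids
  ), class = "pairwise_alignment")
}

# Internal: identity between two gapped rows (character strings of equal
# length).  Terminal-gap columns are excluded; internal gaps count either
# per gapped column ("each-gap") or one difference per gap run
# ("one-gap-per-run").
.identity_from_rows <- function(r1, r2, mode = c("each-gap", "one-gap-per-run")) {
  mode <- match.arg(mode)
  a <- strsplit(r1, "", fixed = TRUE)[[1]]
  b <- strsplit(r2, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("alignment rows differ in length")
  ga <- a == "-"
  gb <- b == "-"
  span <- function(g) {
    if (all(g)) stop("alignment row is all gaps")
    range(which(!g))
  }
  sa <- span(ga); sb <- span(gb)
  keep <- seq_along(a) >= max(sa[1], sb[1]) & seq_along(a) <= min(sa[2], sb[2])
  a <- a[keep]; b <- b[keep]; ga <- ga[keep]; gb <- gb[keep]
  both_gap <- ga & gb          # possible when rows are projected from an MSA
  a <- a[!both_gap]; b <- b[!both_gap]
  ga <- ga[!both_gap]; gb <- gb[!both_gap]
  gapcol <- ga | gb
  n_match <- sum(!gapcol & a == b)
  counted <- if (mode == "each-gap") {
    length(a)
  } else {
    r <- rle(gapcol)
    sum(!gapcol) + sum(r$values)
  }
  if (counted == 0) stop("no counted columns in alignment")
  n_match / counted
}

#' Pairwise identity of an alignment
#'
#' Fraction of matching columns among counted columns of a two-row
#' alignment.  Terminal-gap columns (overhangs) are excluded.  Under the
#' default \code{"each-gap"} policy every internal gap column counts as one
#' difference; under \code{"one-gap-per-run"} a run of consecutive gap
#' columns counts as a single difference.
#'
#' @param aln A \code{pairwise_alignment} or a character vector of two
#'   equal-length gapped rows.
#' @param mode Gap-counting policy.
#' @return Identity in [0, 1].
#' @export
pairwise_identity <- function(aln, mode = c("each-gap", "one-gap-per-run")) {
  rows <- if (inherits(aln, "pairwise_alignment")) aln$rows else aln
  if (length(rows) != 2) stop("pairwise identity needs exactly 2 rows")
  .identity_from_rows(rows[1], rows[2], match.arg(mode))
}

#' All-pairs identity distance matrix
#'
#' Aligns every pair of sequences once and returns the symmetric matrix of
#' distances 1 - identity.  The number of alignments performed
#' (n(n-1)/2) is stored in the \code{"n_alignments"} attribute.
#'
#' @param seqs Named character vector of sequences (>= 2).
#' @inheritParams global_align
#' @param mode Gap policy passed to \code{\link{pairwise_identity}}.
#' @return Symmetric numeric matrix with zero diagonal and sequence ids as
#'   dimnames.
#' @export
distance_matrix <- function(seqs, match = 1, mismatch = -1, gap = -2,
                            mode = "each-gap") {
  seqs <- validate_records(seqs)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  ids <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  res <- .nw_align_pairs(seqs[idx[, 1]], seqs[idx[, 2]], match, mismatch, gap)
  ident <- mapply(.identity_from_rows, res$row_a, res$row_b,
                  MoreArgs = list(mode = mode), USE.NAMES = FALSE)
  d[idx] <- 1 - ident
  d[idx[, c(2, 1), drop = FALSE]] <- 1 - ident
  attr(d, "n_alignments") <- n * (n - 1) / 2
  d
}

#' Center-star multiple sequence alignment
#'
#' Progressive star alignment: the center is the sequence minimizing its
#' total distance to all others; every other sequence is aligned pairwise to
#' the center and gaps are propagated ("once a gap, always a gap").
#' Degapping any row recovers the input sequence exactly.
#'
#' @param seqs Named character vector of sequences (>= 2).
#' @inheritParams distance_matrix
#' @return Character matrix of single characters is not used; rows are
#'   gapped strings: a character matrix with one row per sequence
#'   (rownames = ids) and one column per alignment column, of class
#'   \code{msa}.
#' @export
center_star_msa <- function(seqs, match = 1, mismatch = -1, gap = -2,
                            mode = "each-gap") {
  seqs <- validate_records(seqs)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  dm <- distance_matrix(seqs, match, mismatch, gap, mode)
  sums <- rowSums(dm)
  ord <- order(sums, names(seqs))          # lexicographic tie-break
  center_id <- names(seqs)[ord[1]]
  center <- seqs[[center_id]]
  others <- setdiff(names(seqs), center_id)
  L <- nchar(center)
  center_res <- strsplit(center, "", fixed = TRUE)[[1]]
  aln <- if (length(others))
    .nw_align_pairs(unname(seqs[others]), rep(center, length(others)),
                    match, mismatch, gap)
  # For each other sequence record, per "slot" s (before residue s+1 of the
  # center; slot L after the last), the inserted characters, plus the
  # character aligned to each center residue.
  ins_chars <- list(); res_chars <- list()
  for (oi in seq_along(others)) {
    id <- others[oi]
    oc <- strsplit(aln$row_a[oi], "", fixed = TRUE)[[1]]
    cc <- strsplit(aln$row_b[oi], "", fixed = TRUE)[[1]]
    ins <- vector("list", L + 1)
    for (s in seq_len(L + 1)) ins[[s]] <- character(0)
    res <- character(L)
    cnt <- 0
    for (k in seq_along(cc)) {
      if (cc[k] == "-") {
        ins[[cnt + 1]] <- c(ins[[cnt + 1]], oc[k])
      } else {
        cnt <- cnt + 1
        res[cnt] <- oc[k]
      }
    }
    ins_chars[[id]] <- ins
    res_chars[[id]] <- res
  }
  slot_width <- integer(L + 1)
  for (id in others)
    slot_width <- pmax(slot_width, lengths(ins_chars[[id]]))
  build_row <- function(res, ins) {
    out <- character(0)
    for (s in seq_len(L + 1)) {
      chars <- ins[[s]]
      out <- c(out, chars, rep("-", slot_width[s] - length(chars)))
      if (s <= L) out <- c(out, res[s])
    }
    out
  }
  empty_ins <- rep(list(character(0)), L + 1)
  rows <- c(stats::setNames(list(build_row(center_res, empty_ins)), center_id),
            lapply(stats::setNames(others, others), function(id)
              build_row(res_chars[[id]], ins_chars[[id]])))
  m <- do.call(rbind, rows[names(seqs)])     # keep input order
  rownames(m) <- names(seqs)
  class(m) <- c("msa", class(m))
  attr(m, "center") <- center_id
  m
}

#' Remove gaps from MSA rows
#'
#' @param msa An \code{msa} character matrix.
#' @return Named character vector of degapped sequences.
#' @export
degap <- function(msa) {
  apply(msa, 1, function(r) paste(r[r != "-"], collapse = ""))
}

#' Cluster sequences into OTUs at a distance threshold
#'
#' Agglomerative hierarchical clustering of an identity-distance matrix,
#' cut at \code{threshold}.  With the default 0.03 this implements
#' operational taxonomic units at 97% similarity.  Labels are processed in
#' lexicographic order so ties are broken deterministically.
#'
#' @param dm Symmetric distance matrix with labels as dimnames.
#' @param threshold Distance cut height in [0, 1] (default 0.03).
#' @param linkage One of \code{"average"} (default), \code{"furthest"},
#'   \code{"nearest"}.
#' @return List of OTUs, each a list with \code{otu_id}, \code{members}
#'   (sorted ids) and \code{representative}.
#' @export
cluster_otus <- function(dm, threshold = 0.03,
                         linkage = c("average", "furthest", "nearest")) {
  linkage <- match.arg(linkage)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  labels <- sort(rownames(dm))
  dm <- dm[labels, labels, drop = FALSE]
  if (length(labels) == 1) {
    grp <- stats::setNames(1L, labels)
  } else {
    method <- c(average = "average", furthest = "complete",
                nearest = "single")[[linkage]]
    hc <- stats::hclust(stats::as.dist(dm), method = method)
    grp <- stats::cutree(hc, h = threshold)
  }
  members <- split(labels, grp)
  # order OTUs by their smallest member id
  members <- members[order(vapply(members, min, character(1)))]
  otus <- vector("list", length(members))
  for (i in seq_along(members)) {
    mem <- sort(members[[i]])
    otus[[i]] <- list(otu_id = sprintf("OTU%04d", i),
                      members = mem,
                      representative = pick_representative(mem, dm))
  }
  otus
}

#' Pick the representative sequence of an OTU
#'
#' The member minimizing its summed distance to all other members; ties
#' broken by lexicographically smallest id.
#'
#' @param members Character vector of member ids (nonempty).
#' @param dm Distance matrix covering the members.
#' @return A single sequence id.
#' @export
pick_representative <- function(members, dm) {
  if (length(members) == 0) stop("empty OTU")
  members <- sort(members)
  if (length(members) == 1) return(members)
  sums <- rowSums(dm[members, members, drop = FALSE])
  members[which.min(sums)]    # which.min takes the first (lexicographic) tie
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  validate_records(stats::setNames(as.character(x), names(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- validate_records(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
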