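# Two-step virtual-taxon delimitation: OTU pre-clustering, grouping of OTU
# representatives by bootstrap-supported clades of an NJ tree, and a
# similarity fallback for representatives left without supported grouping.

#' Configuration for virtual-taxon delimitation
#'
#' @param otu_threshold Distance cut for OTU pre-clustering (default 0.03,
#'   i.e. 97\% similarity).
#' @param support_threshold Bootstrap support needed to accept a clade as a
#'   grouping unit, in percent (default 50).
#' @param similarity_threshold Identity required both inside a merged group
#'   and for fallback assignment (default 0.90).
#' @param linkage Linkage for OTU clustering (default "average").
#' @param bootstrap_reps Bootstrap replicates for clade support (default 100).
#' @param seed Optional integer seed controlling the bootstrap.
#' @return A \code{vt_config} list.
#' @export
vt_config <- function(otu_threshold = 0.03, support_threshold = 50,
                      similarity_threshold = 0.90, linkage = "average",
                      bootstrap_reps = 100, seed = NULL) {
  if (otu_threshold < 0 || otu_threshold > 1 - similarity_threshold)
    stop("need 0 <= otu_threshold <= 1 - similarity_threshold")
  if (similarity_threshold < 0 || similarity_threshold > 1)
    stop("similarity_threshold must be in [0, 1]")
  if (support_threshold < 0 || support_threshold > 100)
    stop("support_threshold must be in [0, 100]")
  if (bootstrap_reps < 1) stop("bootstrap_reps must be >= 1")
  structure(list(otu_threshold = otu_threshold,
                 support_threshold = support_threshold,
                 similarity_threshold = similarity_threshold,
                 linkage = linkage,
                 bootstrap_reps = bootstrap_reps,
                 seed = seed), class = "vt_config")
}

#' Assign orphan representatives to groups by similarity
#'
#' Each orphan, processed in lexicographic order, joins the group holding
#' its most similar representative provided that identity meets
#' \code{threshold}; otherwise it seeds a new singleton group (which later
#' orphans may join).
#'
#' @param orphans Character vector of representative ids.
#' @param groups List of character vectors (current groups of rep ids).
#' @param dm Distance matrix over all representative ids (distance =
#'   1 - identity).
#' @param threshold Identity threshold in [0, 1] (default 0.90).
#' @return List with \code{groups} (updated list) and \code{provenance}
#'   (named character vector per orphan: "similarity" if it joined or was
#'   joined, "singleton" if it remained alone).
#' @export
assign_by_similarity <- function(orphans, groups, dm, threshold = 0.90) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  orphans <- sort(orphans)
  joined <- stats::setNames(rep(FALSE, length(orphans)), orphans)
  for (o in orphans) {
    reps <- unlist(groups)
    if (length(reps) > 0) {
      ident <- 1 - dm[o, reps]
      best <- max(ident)
      if (best >= threshold) {
        best_rep <- sort(reps[ident == best])[1]   # lexicographic tie-break
        gi <- which(vapply(groups, function(g) best_rep %in% g, logical(1)))[1]
        groups[[gi]] <- c(groups[[gi]], o)
        joined[o] <- TRUE
        # any orphan that seeded this group is now part of a joined pair
        joined[names(joined) %in% groups[[gi]]] <- TRUE
        next
      }
    }
    groups <- c(groups, list(o))
  }
  prov <- ifelse(joined, "similarity", "singleton")
  list(groups = groups, provenance = stats::setNames(prov, orphans))
}

#' Delimit virtual taxa from ITS sequences
#'
#' The full two-step procedure: (1) all-pairs identity distances and
#' agglomerative OTU clustering at \code{otu_threshold}; (2) one
#' representative per OTU, center-star alignment of representatives,
#' bootstrap NJ tree, and bottom-up agglomeration of representatives along
#' supported clades, every merge additionally gated by the requirement that
#' all representatives of the merged group be mutually at least
#' \code{similarity_threshold} identical; (3) representatives left in
#' singleton groups fall back to similarity assignment at the same
#' threshold; finally, any two groups whose representatives are all
#' mutually within the similarity envelope are merged, so clade fragments
#' that only reached partial support still join by similarity.  Final
#' groups, expanded to their OTU members, are the virtual taxa.
#'
#' The whole representative set is always a candidate group (gated by the
#' same identity envelope), so when every representative is mutually above
#' the similarity threshold the taxa collapse into one VT, and inputs of
#' 1-3 sequences are grouped purely by similarity.
#'
#' @param seqs Named character vector of sequences.
#' @param cfg A \code{\link{vt_config}}.
#' @return A \code{vt_assignment}: list with \code{vts} (named list vt_id ->
#'   sorted member ids), \code{representatives} (named character vector
#'   vt_id -> representative id), \code{provenance} (named character vector
#'   per sequence: "clade", "similarity" or "singleton"), \code{otus},
#'   \code{tree} (the representative \code{support_tree}, or NULL when the
#'   tree stage was skipped), and \code{config}.
#' @export
delimit_vts <- function(seqs, cfg = vt_config()) {
  seqs <- validate_records(seqs)
  n <- length(seqs)
  if (n == 1) {
    id <- names(seqs)
    return(structure(list(
      vts = stats::setNames(list(id), "VT0001"),
      representatives = c(VT0001 = id),
      provenance = stats::setNames("singleton", id),
      otus = list(list(otu_id = "OTU0001", members = id,
                       representative = id)),
      tree = NULL, config = cfg), class = "vt_assignment"))
  }
  dm <- distance_matrix(seqs)
  otus <- cluster_otus(dm, threshold = cfg$otu_threshold,
                       linkage = cfg$linkage)
  reps <- vapply(otus, `[[`, character(1), "representative")
  rep_dm <- dm[reps, reps, drop = FALSE]
  sim <- 1 - rep_dm

  groups <- as.list(sort(reps))
  grp_prov <- rep("singleton", length(groups))
  tree <- NULL

  # candidate clades: supported bipartition sides of the representative
  # bootstrap tree (when it exists), plus the trivial whole-set candidate
  if (length(reps) >= 4) {
    msa <- center_star_msa(seqs[reps])
    tree <- bootstrap_support(msa, n_reps = cfg$bootstrap_reps,
                              seed = cfg$seed)
    clades <- supported_clades(tree, cfg$support_threshold)
  } else {
    clades <- list()
  }
  clades <- c(clades, list(sort(reps)))

  gate <- function(ids) {
    if (length(ids) < 2) return(TRUE)
    s <- sim[ids, ids]
    all(s[upper.tri(s)] >= cfg$similarity_threshold)
  }
  for (cl in clades) {
    inside <- vapply(groups, function(g) all(g %in% cl), logical(1))
    covered <- sort(unlist(groups[inside]))
    if (!identical(covered, sort(cl))) next     # clade split across groups
    if (sum(inside) < 2) next
    if (!gate(cl)) next
    groups <- c(groups[!inside], list(covered))
    grp_prov <- c(grp_prov[!inside], "clade")
  }

  orphans <- unlist(groups[grp_prov == "singleton" &
                             lengths(groups) == 1])
  kept <- grp_prov != "singleton" | lengths(groups) > 1
  fb <- assign_by_similarity(orphans, groups[kept], rep_dm,
                             threshold = cfg$similarity_threshold)
  groups <- fb$groups
  grp_prov <- c(grp_prov[kept], rep(NA_character_,
                                    length(groups) - sum(kept)))

  # provenance per representative
  rep_prov <- stats::setNames(rep(NA_character_, length(reps)), sort(reps))
  for (gi in seq_along(groups)) {
    for (r in groups[[gi]]) {
      rep_prov[r] <- if (r %in% names(fb$provenance)) {
        fb$provenance[[r]]
      } else if (!is.na(grp_prov[gi]) && grp_prov[gi] == "clade") {
        "clade"
      } else if (length(groups[[gi]]) > 1) {
        "similarity"
      } else {
        "singleton"
      }
    }
  }

  # group-level similarity fallback: clade fragments of one taxon can end
  # up as separate multi-representative groups when only sub-clades reach
  # the support threshold; any two groups whose representatives are all
  # mutually within the similarity envelope are therefore merged
  # (deterministically, first eligible pair in sorted order) until a fixed
  # point is reached
  groups <- lapply(groups, sort)
  repeat {
    groups <- groups[order(vapply(groups, min, character(1)))]
    merged <- FALSE
    ng <- length(groups)
    if (ng >= 2) {
      for (i in seq_len(ng - 1)) {
        for (j in (i + 1):ng) {
          cross <- sim[groups[[i]], groups[[j]], drop = FALSE]
          if (all(cross >= cfg$similarity_threshold)) {
            rep_prov[c(groups[[i]], groups[[j]])[
              rep_prov[c(groups[[i]], groups[[j]])] == "singleton"]] <-
              "similarity"
            groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  # expand representative groups to OTU members
  otu_by_rep <- stats::setNames(lapply(otus, `[[`, "members"), reps)
  vts <- lapply(groups, function(g) sort(unlist(otu_by_rep[g])))
  ord <- order(vapply(vts, min, character(1)))
  vts <- vts[ord]
  groups <- groups[ord]
  names(vts) <- sprintf("VT%04d", seq_along(vts))

  vt_reps <- vapply(vts, pick_representative, character(1), dm = dm)
  seq_prov <- stats::setNames(rep(NA_character_, n), names(seqs))
  for (vi in seq_along(vts)) {
    for (r in groups[[vi]])
      seq_prov[otu_by_rep[[r]]] <- rep_prov[[r]]
  }
  structure(list(vts = vts, representatives = vt_reps,
                 provenance = seq_prov, otus = otus, tree = tree,
                 config = cfg), class = "vt_assignment")
}

#' Summarize a virtual-taxon assignment
#'
#' @param assignment A \code{vt_assignment} (or bare list of member-id
#'   vectors).
#' @return List with \code{n_vts}, \code{n_singletons}, \code{n_doubletons}
#'   and \code{size_histogram} (table of VT sizes).
#' @export
vt_summary <- function(assignment) {
  vts <- if (inherits(assignment, "vt_assignment")) assignment$vts
         else assignment
  sizes <- lengths(vts)
  list(n_vts = length(vts),
       n_singletons = sum(sizes == 1),
       n_doubletons = sum(sizes == 2),
       size_histogram = if (length(sizes)) table(sizes) else table(integer(0)))
}

#' Per-sequence VT membership vector
#'
#' @param assignment A \code{vt_assignment}.
#' @return Named character vector: sequence id -> vt_id.
#' @export
vt_membership <- function(assignment) {
  stopifnot(inherits(assignment, "vt_assignment"))
  out <- unlist(lapply(names(assignment$vts), function(v)
    stats::setNames(rep(v, length(assignment$vts[[v]])),
                    assignment$vts[[v]])))
  out[sort(names(out))]
}

#' @export
print.vt_assignment <- function(x, ...) {
  s <- vt_summary(x)
  cat(sprintf("vt_assignment: %d sequences in %d VTs (%d singletons, %d doubletons)\n",
              sum(lengths(x$vts)), s$n_vts, s$n_singletons, s$n_doubletons))
  invisible(x)
}
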