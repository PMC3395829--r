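# Seeded generators: ITS-like sequence sets with planted taxon structure,
# categorical metadata with controlled endemism, and linear-Gaussian tables
# for the path model.  Ground truth is returned alongside so downstream
# stages can be validated against it.

.DEFAULT_HOST_ORDERS <- c("Asterales", "Fabales", "Lamiales", "Malpighiales",
                          "Pinales", "Poales", "Rosales", "Solanales")

#' Configuration for the sequence generator
#'
#' @param n_taxa Number of planted taxa (>= 1).
#' @param members Members per taxon: an integer vector (recycled), or NULL
#'   to draw from a geometric distribution (so singletons and doubletons
#'   arise naturally, as in uneven sequence archives).
#' @param mean_members Mean of the geometric member-count distribution
#'   (default 3), used when \code{members} is NULL.
#' @param seq_length Sequence length in bases (>= 50, default 400).
#' @param intra_mut Per-site substitution probability of a member relative
#'   to its taxon ancestor (default 0.02).
#' @param inter_div Minimum per-site divergence required between taxon
#'   ancestors (default 0.20).  Must satisfy
#'   0 <= intra_mut < inter_div <= 0.75.
#' @param indel_rate Per-site insertion/deletion probability for members
#'   (default 0: planted identities stay analytically controllable).
#' @param seed Optional integer seed.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_taxa, members = NULL, mean_members = 3,
                         seq_length = 400, intra_mut = 0.02,
                         inter_div = 0.20, indel_rate = 0, seed = NULL) {
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  if (seq_length < 50) stop("seq_length must be >= 50")
  if (!(intra_mut >= 0 && intra_mut < inter_div && inter_div <= 0.75))
    stop("need 0 <= intra_mut < inter_div <= 0.75")
  if (mean_members < 1) stop("mean_members must be >= 1")
  structure(list(n_taxa = n_taxa, members = members,
                 mean_members = mean_members, seq_length = seq_length,
                 intra_mut = intra_mut, inter_div = inter_div,
                 indel_rate = indel_rate, seed = seed),
            class = "synth_config")
}

# Internal: substitute each site independently with probability rate, to
# one of the three other bases uniformly (Jukes-Cantor-like), matching the
# JC-corrected distances used downstream.
.mutate <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(chars[hit],
                   function(b) sample(setdiff(bases, b), 1), character(1))
    chars[hit] <- repl
  }
  chars
}

.apply_indels <- function(chars, rate) {
  if (rate <= 0) return(chars)
  del <- stats::runif(length(chars)) < rate / 2
  ins <- stats::runif(length(chars)) < rate / 2
  out <- character(0)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(chars)) {
    if (!del[i]) out <- c(out, chars[i])
    if (ins[i]) out <- c(out, sample(bases, 1))
  }
  if (length(out) == 0) chars else out
}

#' Generate sequences with planted taxon structure
#'
#' Taxon ancestors are derived from a common random root mutated at rate
#' \code{inter_div}; the set is re-drawn (bounded retries) until all
#' pairwise ancestor divergences are at least \code{inter_div}.  Each
#' member is its ancestor mutated i.i.d. at rate \code{intra_mut}
#' (plus optional indels).  Fully deterministic under a fixed seed.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return List with \code{records} (named character vector of sequences,
#'   ids "T<taxon>S<member>") and \code{truth} (list per taxon:
#'   \code{taxon_id}, \code{member_ids}, \code{ancestor}).
#' @export
generate_taxa <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  L <- cfg$seq_length
  K <- cfg$n_taxa
  max_retry <- 25
  for (attempt in seq_len(max_retry)) {
    root <- sample(bases, L, replace = TRUE)
    ancestors <- lapply(seq_len(K), function(i) .mutate(root, cfg$inter_div))
    ok <- TRUE
    if (K > 1) {
      for (i in seq_len(K - 1)) for (j in (i + 1):K) {
        if (mean(ancestors[[i]] != ancestors[[j]]) < cfg$inter_div) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) break
    if (attempt == max_retry)
      stop("could not place ", K, " ancestors at divergence >= ",
           cfg$inter_div, " after ", max_retry, " attempts")
  }
  m <- if (is.null(cfg$members)) {
    stats::rgeom(K, prob = 1 / cfg$mean_members) + 1L
  } else {
    rep_len(as.integer(cfg$members), K)
  }
  records <- character(0)
  truth <- vector("list", K)
  for (t in seq_len(K)) {
    ids <- sprintf("T%02dS%02d", t, seq_len(m[t]))
    seqs <- vapply(seq_len(m[t]), function(s) {
      chars <- .mutate(ancestors[[t]], cfg$intra_mut)
      chars <- .apply_indels(chars, cfg$indel_rate)
      paste(chars, collapse = "")
    }, character(1))
    records <- c(records, stats::setNames(seqs, ids))
    truth[[t]] <- list(taxon_id = sprintf("TAX%02d", t),
                       member_ids = ids,
                       ancestor = paste(ancestors[[t]], collapse = ""))
  }
  list(records = records, truth = truth)
}

#' Configuration for the metadata generator
#'
#' @param endemism_fraction Proportion of taxa confined to exactly one
#'   label of every scheme (and one location), in [0, 1]; default 0.8.
#' @param n_locations Number of sampling locations (default 8).
#' @param seed Optional integer seed.
#' @param host_orders Host plant order labels (free-form vocabulary).
#' @param origin_probs Sampling probabilities for sequence origin
#'   (root/soil/spore); defaults emphasise roots, where host identity is
#'   known.
#' @return A \code{meta_config} list.
#' @export
meta_config <- function(endemism_fraction = 0.8, n_locations = 8,
                        seed = NULL, host_orders = .DEFAULT_HOST_ORDERS,
                        origin_probs = c(root = 0.7, soil = 0.2,
                                         spore = 0.1)) {
  if (endemism_fraction < 0 || endemism_fraction > 1)
    stop("endemism_fraction must be in [0, 1]")
  if (n_locations < 1) stop("n_locations must be >= 1")
  structure(list(endemism_fraction = endemism_fraction,
                 n_locations = n_locations, seed = seed,
                 host_orders = host_orders, origin_probs = origin_probs),
            class = "meta_config")
}

#' Attach planted categorical metadata to generated taxa
#'
#' Every sequence receives one label per scheme (host order, functional
#' group, ecosystem, continent, realm, climate), a location id and an
#' origin.  A fraction \code{endemism_fraction} of taxa is endemic: all
#' members share a single label per scheme and one location.  The
#' remaining taxa (drawn among taxa with >= 2 members; singleton taxa are
#' necessarily single-label) spread their members over exactly two labels
#' of every scheme, both guaranteed to occur.  Primary labels are assigned
#' by shuffled recycling, so every label of a scheme is used whenever
#' n_taxa >= number of labels.
#'
#' @param truth Taxon truth list from \code{\link{generate_taxa}}.
#' @param mcfg A \code{\link{meta_config}}.
#' @return Metadata data.frame (columns as in
#'   \code{\link{read_metadata}}), with the endemic taxon ids in attribute
#'   \code{"endemic_taxa"}.
#' @export
attach_metadata <- function(truth, mcfg = meta_config()) {
  stopifnot(inherits(mcfg, "meta_config"))
  if (!is.null(mcfg$seed)) set.seed(mcfg$seed)
  K <- length(truth)
  vocab <- metadata_vocabulary()
  schemes <- list(host_order = mcfg$host_orders,
                  functional_group = vocab$functional_group,
                  ecosystem = vocab$ecosystem,
                  continent = vocab$continent,
                  realm = vocab$realm,
                  climate = vocab$climate,
                  location_id = sprintf("L%02d", seq_len(mcfg$n_locations)))
  sizes <- lengths(lapply(truth, `[[`, "member_ids"))
  n_multi_target <- K - round(mcfg$endemism_fraction * K)
  multi_capable <- which(sizes >= 2)
  if (n_multi_target > length(multi_capable)) {
    warning("not enough multi-member taxa to realise the requested ",
            "endemism fraction exactly")
    n_multi_target <- length(multi_capable)
  }
  non_endemic <- if (n_multi_target > 0)
    sort(sample(multi_capable, n_multi_target)) else integer(0)

  rows <- vector("list", K)
  for (t in seq_len(K)) {
    ids <- truth[[t]]$member_ids
    rows[[t]] <- data.frame(seq_id = ids, stringsAsFactors = FALSE)
  }
  for (sname in names(schemes)) {
    labels <- schemes[[sname]]
    primary <- sample(rep_len(labels, K))          # every label covered
    for (t in seq_len(K)) {
      m <- sizes[t]
      lab <- rep(primary[t], m)
      if (t %in% non_endemic && length(labels) >= 2) {
        second <- sample(setdiff(labels, primary[t]), 1)
        lab[2] <- second
        if (m > 2)
          lab[3:m] <- sample(c(primary[t], second), m - 2, replace = TRUE)
      }
      rows[[t]][[sname]] <- lab
    }
  }
  meta <- do.call(rbind, rows)
  meta$origin <- sample(names(mcfg$origin_probs), nrow(meta),
                        replace = TRUE, prob = mcfg$origin_probs)
  meta <- meta[, .META_COLUMNS]
  meta <- .validate_metadata(meta)
  attr(meta, "endemic_taxa") <- vapply(setdiff(seq_len(K), non_endemic),
                                       function(t) truth[[t]]$taxon_id, "")
  meta
}

#' Generate linear-Gaussian data for the path model
#'
#' Exogenous factors are standard (optionally correlated) Gaussians; plant
#' and amf are linear in their parents with Gaussian residuals whose
#' variances are set so every variable has unit population variance --
#' the planted coefficients are therefore population standardized path
#' coefficients.  Sample columns are z-scored.
#'
#' @param n Sample size.
#' @param coeffs Named numeric vector of planted standardized coefficients,
#'   names of the form \code{"from->to"} (e.g. \code{"plant->amf"}).
#'   Unnamed edges of the full recursive model default to 0.
#' @param seed Optional integer seed.
#' @param exo_cor Correlation matrix of the four exogenous factors
#'   (default identity).
#' @return Data.frame with columns ecosystem, climate, continent,
#'   biogeography, plant, amf; the planted coefficient vector is attached
#'   as attribute \code{"coeffs"}.
#' @export
generate_path_data <- function(n, coeffs = NULL, seed = NULL,
                               exo_cor = diag(4)) {
  spec <- path_spec()          # validates recursivity of the full edge set
  full <- stats::setNames(rep(0, nrow(spec$edges)),
                          paste0(spec$edges$from, "->", spec$edges$to))
  if (!is.null(coeffs)) {
    bad <- setdiff(names(coeffs), names(full))
    if (length(bad))
      stop("not an edge of the recursive model: ",
           paste(bad, collapse = ", "))
    full[names(coeffs)] <- coeffs
  }
  if (!is.null(seed)) set.seed(seed)
  exo <- spec$exogenous
  dimnames(exo_cor) <- list(exo, exo)
  Z <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(exo_cor)
  colnames(Z) <- exo
  bp <- full[paste0(exo, "->plant")]
  var_expl_p <- drop(t(bp) %*% exo_cor %*% bp)
  if (var_expl_p >= 1) stop("planted coefficients imply variance >= 1 for plant")
  plant <- drop(Z %*% bp) + stats::rnorm(n, sd = sqrt(1 - var_expl_p))
  ba <- full[paste0(exo, "->amf")]
  bpa <- full["plant->amf"]
  # population covariance of predictors (exo, plant)
  Sxp <- exo_cor %*% bp
  Sxx <- rbind(cbind(exo_cor, Sxp), cbind(t(Sxp), 1))
  bfull <- c(ba, bpa)
  var_expl_a <- drop(t(bfull) %*% Sxx %*% bfull)
  if (var_expl_a >= 1) stop("planted coefficients imply variance >= 1 for amf")
  amf <- drop(Z %*% ba) + bpa * plant +
    stats::rnorm(n, sd = sqrt(1 - var_expl_a))
  out <- data.frame(Z, plant = plant, amf = amf)
  out[] <- lapply(out, function(x) as.numeric(scale(x)))
  attr(out, "coeffs") <- full
  out
}
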