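# Rarefaction, specificity/endemism, host-range regression, Bray-Curtis,
# Mantel test and composition-similarity regression.  NMDS lives in
# nmds.R.

#' Rarefaction curve of virtual-taxon richness
#'
#' At each depth n, the mean and percentile confidence interval of the
#' number of distinct VTs in a random subsample of n sequences without
#' replacement, over \code{n_iter} draws (one random permutation per
#' iteration; its prefixes are uniform subsamples, which keeps the curve
#' monotone within every iteration).  The closed-form hypergeometric
#' expectation E[S_n] = sum_v (1 - C(N-N_v, n)/C(N, n)) is computed
#' alongside for cross-checking.
#'
#' @param vt_per_seq Character vector: the VT of every sequence.
#' @param depths Integer vector of subsample sizes (default 1..N).
#' @param n_iter Number of randomizations (default 1000).
#' @param seed Optional integer seed.
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @return A data.frame of class \code{rarefaction_curve} with columns
#'   \code{depth}, \code{mean_richness}, \code{ci_low}, \code{ci_high},
#'   \code{expected} (closed form) and \code{se_mean} (Monte-Carlo standard
#'   error of the mean).
#' @export
rarefaction <- function(vt_per_seq, depths = NULL, n_iter = 1000,
                        seed = NULL, conf = 0.95) {
  if (length(vt_per_seq) < 1) stop("need at least one sequence")
  N <- length(vt_per_seq)
  if (is.null(depths)) depths <- seq_len(N)
  if (any(depths < 1 | depths > N)) stop("depths must lie in 1..N")
  depths <- sort(unique(as.integer(depths)))
  if (!is.null(seed)) set.seed(seed)
  rich <- matrix(0L, n_iter, length(depths))
  for (it in seq_len(n_iter)) {
    perm <- vt_per_seq[sample.int(N)]
    cum <- cumsum(!duplicated(perm))
    rich[it, ] <- cum[depths]
  }
  counts <- table(vt_per_seq)
  expected <- vapply(depths, function(n)
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n))), numeric(1))
  alpha <- (1 - conf) / 2
  out <- data.frame(
    depth = depths,
    mean_richness = colMeans(rich),
    ci_low = apply(rich, 2, stats::quantile, probs = alpha),
    ci_high = apply(rich, 2, stats::quantile, probs = 1 - alpha),
    expected = expected,
    se_mean = apply(rich, 2, stats::sd) / sqrt(n_iter)
  )
  rownames(out) <- NULL
  class(out) <- c("rarefaction_curve", "data.frame")
  attr(out, "n_iter") <- n_iter
  out
}

#' Endemism / specificity of virtual taxa over a category scheme
#'
#' Overall endemism is the fraction of VTs (rows) occurring in exactly one
#' category (column).  Per-column specificity is, for each category, the
#' fraction of its VTs that occur nowhere else -- the "host plant
#' selectivity" when columns are host taxonomic orders.
#'
#' @param m Incidence matrix (counts or presence).
#' @return List with \code{overall} (scalar) and \code{per_column} (named
#'   numeric vector).
#' @export
specificity <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0)
    stop("empty incidence matrix")
  P <- m > 0
  n_cols <- rowSums(P)
  exclusive <- n_cols == 1
  per_col <- vapply(seq_len(ncol(P)), function(j) {
    in_col <- P[, j]
    if (!any(in_col)) return(NA_real_)
    sum(in_col & exclusive) / sum(in_col)
  }, numeric(1))
  list(overall = mean(exclusive),
       per_column = stats::setNames(per_col, colnames(P)))
}

#' Host range versus geographical range of virtual taxa
#'
#' For every VT with at least one root-derived sequence, x = number of
#' distinct host orders and y = number of distinct locations; ordinary
#' least squares of y on x with the exact F-test p-value.
#'
#' @param assignment A \code{vt_assignment}.
#' @param meta Metadata data.frame.
#' @param origin Origin filter (default \code{"root"}: host identity is only
#'   meaningful for sequences recovered from roots).
#' @return A \code{regression_result}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_value}, \code{n} and the
#'   per-VT \code{data}.
#' @export
host_range_vs_geo <- function(assignment, meta, origin = "root") {
  membership <- vt_membership(assignment)
  rownames(meta) <- meta$seq_id
  meta <- meta[meta$origin %in% origin, , drop = FALSE]
  membership <- membership[names(membership) %in% rownames(meta)]
  if (length(membership) == 0) stop("no sequences pass the origin filter")
  meta <- meta[names(membership), , drop = FALSE]
  split_idx <- split(seq_len(nrow(meta)), membership)
  x <- vapply(split_idx, function(i) length(unique(meta$host_order[i])),
              numeric(1))
  y <- vapply(split_idx, function(i) length(unique(meta$location_id[i])),
              numeric(1))
  if (length(x) < 3) stop("need at least 3 VTs for regression")
  .ols_result(x, y, data = data.frame(vt_id = names(x), host_range = x,
                                      geo_range = y))
}

# Internal: simple OLS y ~ x with F-test p-value.
.ols_result <- function(x, y, data = NULL) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p,
                 n = length(x),
                 data = data), class = "regression_result")
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y), computed with
#' \code{vegan::vegdist}.  A pair of all-zero vectors has dissimilarity 0
#' by convention (logged via message).
#'
#' @param m Nonnegative count (or presence) matrix.
#' @param by Compare \code{"rows"} (default) or \code{"columns"}.
#' @return Symmetric dissimilarity matrix in [0, 1] with labels.
#' @export
bray_curtis <- function(m, by = c("rows", "columns")) {
  by <- match.arg(by)
  if (any(m < 0)) stop("negative entries are not allowed")
  if (by == "columns") m <- t(m)
  mode(m) <- "numeric"
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  d <- as.matrix(d)
  if (anyNA(d)) {
    message("all-zero unit pair(s): Bray-Curtis set to 0 by convention")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle vectors, with significance
#' from simultaneous row/column permutations of the second matrix
#' (one-sided, positive association), via \code{vegan::mantel}.  The
#' p-value is (1 + #\{permuted r >= observed\}) / (1 + n_perm).
#'
#' @param dm1,dm2 Distance matrices over the same labels in the same order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param tail Only \code{"positive"} is supported.
#' @return A \code{mantel_result}: list with \code{r}, \code{p},
#'   \code{n_perm}.
#' @export
mantel <- function(dm1, dm2, n_perm = 999, seed = NULL, tail = "positive") {
  tail <- match.arg(tail, "positive")
  l1 <- rownames(as.matrix(dm1)); l2 <- rownames(as.matrix(dm2))
  if (!identical(l1, l2))
    stop("distance matrices must share the same labels in the same order")
  if (!is.null(seed)) set.seed(seed)
  v <- vegan::mantel(stats::as.dist(as.matrix(dm1)),
                     stats::as.dist(as.matrix(dm2)),
                     method = "pearson", permutations = n_perm)
  structure(list(r = unname(v$statistic), p = unname(v$signif),
                 n_perm = n_perm), class = "mantel_result")
}

#' Regression of VT composition similarity on plant composition similarity
#'
#' For every unordered pair of categories (columns), x = Bray-Curtis
#' similarity (1 - dissimilarity) of the plant-order composition and y =
#' the same for the VT composition; ordinary least squares of y on x.
#'
#' @param vt_matrix VT x category count matrix.
#' @param plant_matrix Plant-order x category count matrix with the same
#'   categories.
#' @return A \code{regression_result}; \code{data} holds one row per
#'   category pair.
#' @export
composition_similarity_regression <- function(vt_matrix, plant_matrix) {
  cats <- colnames(vt_matrix)
  if (!setequal(cats, colnames(plant_matrix)))
    stop("matrices must cover the same categories")
  plant_matrix <- plant_matrix[, cats, drop = FALSE]
  if (length(cats) < 3) stop("need at least 3 categories")
  bc_v <- bray_curtis(vt_matrix, by = "columns")
  bc_p <- bray_curtis(plant_matrix, by = "columns")
  pairs <- utils::combn(cats, 2)
  x <- 1 - bc_p[cbind(pairs[1, ], pairs[2, ])]
  y <- 1 - bc_v[cbind(pairs[1, ], pairs[2, ])]
  .ols_result(x, y, data = data.frame(cat1 = pairs[1, ], cat2 = pairs[2, ],
                                      plant_similarity = x,
                                      vt_similarity = y))
}
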