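# Non-metric multidimensional scaling by minimization of Kruskal's
# stress-1, alternating monotone (isotonic) regression of configuration
# distances on the dissimilarity ranks with Guttman-transform majorization
# steps.  Multiple starts: classical scaling first, then seeded random
# configurations.

#' Kruskal stress-1 of a configuration
#'
#' sqrt(sum (d - dhat)^2 / sum d^2), where d are the configuration
#' distances and dhat the best monotone (isotonic) fit of d to the order of
#' the dissimilarities (primary tie treatment).
#'
#' @param points n x k coordinate matrix.
#' @param dm Dissimilarity matrix (n x n) or dist.
#' @return Stress-1 value in [0, 1].
#' @export
stress1 <- function(points, dm) {
  delta <- as.vector(stats::as.dist(as.matrix(dm)))
  d <- as.vector(stats::dist(points))
  dhat <- .monotone_fit(delta, d)
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

# Internal: isotonic fit of d against the order of delta (ties in delta
# broken by ascending d = primary treatment).
.monotone_fit <- function(delta, d) {
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  dhat[ord] <- stats::isoreg(d[ord])$yf
  dhat
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal's stress-1 over \code{n_starts} initial
#' configurations: the first is classical (metric) scaling, the rest are
#' seeded random Gaussian configurations.  Each start alternates an
#' isotonic-regression step with a Guttman majorization step and stops when
#' the stress decrease falls below \code{tol}; an update that would
#' increase the stress is rejected, so the per-iteration stress trace is
#' non-increasing by construction.  The reported stress is stress-1
#' evaluated at the returned configuration.
#'
#' @param dm Dissimilarity matrix (or dist) over >= 3 units.
#' @param k Target dimension (default 2), must be < n.
#' @param n_starts Number of initial configurations (default 20).
#' @param max_iter Maximum iterations per start (default 200).
#' @param tol Convergence tolerance on the stress decrease (default 1e-6).
#' @param seed Optional integer seed.
#' @return An \code{nmds_result}: list with \code{points} (n x k, labelled),
#'   \code{stress}, \code{stress_trace} (per-iteration stress of the best
#'   start), \code{converged} (logical; FALSE carries a warning),
#'   \code{n_starts}, \code{start_stresses}.
#' @export
nmds <- function(dm, k = 2, n_starts = 20, max_iter = 200, tol = 1e-6,
                 seed = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (k >= n) stop("k must be smaller than the number of units")
  if (n < 3) stop("need at least 3 units")
  labels <- rownames(dm)
  delta <- as.vector(stats::as.dist(dm))
  if (!is.null(seed)) set.seed(seed)

  run_start <- function(X) {
    trace <- numeric(0)
    d <- as.vector(stats::dist(X))
    dhat <- .monotone_fit(delta, d)
    s <- sqrt(sum((d - dhat)^2) / sum(d^2))
    trace <- s
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      if (s < 1e-12) { converged <- TRUE; break }
      Dm <- as.matrix(stats::dist(X))
      Dh <- matrix(0, n, n)
      Dh[lower.tri(Dh)] <- dhat
      Dh <- Dh + t(Dh)
      ratio <- ifelse(Dm > 0, Dh / Dm, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      Xn <- B %*% X / n
      dn <- as.vector(stats::dist(Xn))
      dhn <- .monotone_fit(delta, dn)
      sn <- sqrt(sum((dn - dhn)^2) / sum(dn^2))
      if (!is.finite(sn) || sn > s + 1e-12) { converged <- TRUE; break }
      improved <- s - sn
      X <- Xn; d <- dn; dhat <- dhn; s <- sn
      trace <- c(trace, s)
      if (improved < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = s, trace = trace, converged = converged)
  }

  starts <- vector("list", n_starts)
  cmds <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k))
  if (ncol(cmds) < k)
    cmds <- cbind(cmds, matrix(0, n, k - ncol(cmds)))
  starts[[1]] <- run_start(cmds)
  if (n_starts > 1) {
    for (i in 2:n_starts)
      starts[[i]] <- run_start(matrix(stats::rnorm(n * k), n, k))
  }
  stresses <- vapply(starts, `[[`, numeric(1), "stress")
  best <- starts[[which.min(stresses)]]
  if (!best$converged)
    warning("NMDS did not converge within max_iter; returning best so far")
  pts <- best$X
  rownames(pts) <- labels
  structure(list(points = pts, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 n_starts = n_starts, start_stresses = stresses),
            class = "nmds_result")
}
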