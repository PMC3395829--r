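# PCA score construction and recursive path-model (observed-variable SEM)
# fitting: per-equation standardized OLS, direct/indirect/total effect
# decomposition, R-squared, and likelihood-discrepancy fit indices on the
# implied covariance.

.PATH_VARIABLES <- c("ecosystem", "climate", "continent", "biogeography",
                     "plant", "amf")
.PATH_EXOGENOUS <- c("ecosystem", "climate", "continent", "biogeography")

#' First principal-component scores
#'
#' Columns are centered (not scaled); scores are the projection onto the
#' leading eigenvector of the covariance matrix.  The sign is fixed so that
#' the loading of the lexicographically first feature with a nonzero
#' loading is positive, making scores deterministic.
#'
#' @param m Numeric matrix, units x features (>= 2 units, at least one
#'   feature with nonzero variance).  For categorical schemes, one-hot
#'   encode to composition (e.g. row-normalized counts) first.
#' @return Named numeric vector of scores (mean 0), with the loadings as
#'   attribute \code{"loadings"}.
#' @export
pca_first_component <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 units")
  cm <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(cm) < 1e-12)) stop("all features are constant")
  sv <- svd(cm)
  v <- sv$v[, 1]
  ord <- order(colnames(m))
  if (is.null(colnames(m))) ord <- seq_len(ncol(m))
  lead <- ord[which(abs(v[ord]) > 1e-12)[1]]
  if (v[lead] < 0) v <- -v
  scores <- drop(cm %*% v)
  names(scores) <- rownames(m)
  attr(scores, "loadings") <- stats::setNames(v, colnames(m))
  scores
}

#' Row-normalize a count matrix to composition and take PC1 scores
#'
#' @param m Count matrix (units x categories).
#' @return Named score vector (see \code{\link{pca_first_component}}).
#' @export
composition_scores <- function(m) {
  rs <- rowSums(m)
  if (any(rs == 0)) stop("unit(s) with zero total count: ",
                         paste(rownames(m)[rs == 0], collapse = ", "))
  pca_first_component(m / rs)
}

#' Specify a recursive path model
#'
#' Variables are fixed: four exogenous factors (ecosystem, climate,
#' continent, biogeography) with free covariances, and two endogenous
#' variables (plant, amf).  Edges must point from exogenous variables to
#' plant or amf, or from plant to amf, so the model is recursive (acyclic)
#' by construction.
#'
#' @param edges Character vector of \code{"from->to"} edges; NULL gives the
#'   full model (every exogenous -> plant, every exogenous -> amf,
#'   plant -> amf).
#' @return A \code{path_spec}: list with \code{variables}, \code{exogenous},
#'   \code{edges} (data.frame from/to).
#' @export
path_spec <- function(edges = NULL) {
  if (is.null(edges))
    edges <- c(paste0(.PATH_EXOGENOUS, "->plant"),
               paste0(.PATH_EXOGENOUS, "->amf"),
               "plant->amf")
  parts <- strsplit(edges, "->", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("edges must be of the form 'from->to'")
  ed <- data.frame(from = vapply(parts, `[[`, "", 1),
                   to = vapply(parts, `[[`, "", 2))
  if (any(!ed$from %in% .PATH_VARIABLES) || any(!ed$to %in% .PATH_VARIABLES))
    stop("unknown variable in edges")
  if (any(ed$to %in% .PATH_EXOGENOUS))
    stop("exogenous variables cannot be endogenous; model must be recursive")
  if (any(ed$from == "amf"))
    stop("cyclic structure: amf has no descendants in a recursive model")
  if (anyDuplicated(paste(ed$from, ed$to))) stop("duplicate edges")
  structure(list(variables = .PATH_VARIABLES, exogenous = .PATH_EXOGENOUS,
                 edges = ed), class = "path_spec")
}

#' Fit a recursive path model by standardized OLS
#'
#' All six variables are z-scored internally; each endogenous variable
#' (plant, then amf) is regressed on its parents.  For recursive models
#' with observed variables these per-equation least-squares estimates
#' coincide with maximum likelihood in the population.  Indirect effects
#' are products of constituent path coefficients (computed exactly via
#' (I - B)^-1 - I - B), so total = direct + indirect holds as an algebraic
#' identity.
#'
#' @param data Data.frame with columns ecosystem, climate, continent,
#'   biogeography, plant, amf.
#' @param spec A \code{\link{path_spec}}.
#' @return A \code{path_model_result}: list with \code{direct},
#'   \code{indirect}, \code{total} (named vectors over "from->to" pairs
#'   into each endogenous variable), \code{r_squared}, \code{B}
#'   (coefficient matrix), \code{residual_variance}, \code{n},
#'   \code{spec}.
#' @export
fit_path_model <- function(data, spec = path_spec()) {
  vars <- spec$variables
  if (!all(vars %in% names(data))) stop("data must contain all 6 variables")
  Z <- scale(as.matrix(data[, vars]))
  n <- nrow(Z)
  nfree <- length(spec$exogenous) * (length(spec$exogenous) + 1) / 2 +
    nrow(spec$edges) + 2
  if (n <= nfree) stop("more free parameters than observations")
  B <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  r2 <- c(plant = NA_real_, amf = NA_real_)
  resid_var <- c(plant = NA_real_, amf = NA_real_)
  for (y in c("plant", "amf")) {
    parents <- spec$edges$from[spec$edges$to == y]
    if (length(parents) == 0) { r2[y] <- 0; resid_var[y] <- stats::var(Z[, y]); next }
    X <- Z[, parents, drop = FALSE]
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1)
      stop("rank-deficient predictors for ", y, ": check collinearity among ",
           paste(parents, collapse = ", "))
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), Z[, y])
    b <- fit$coefficients[-1]
    B[y, parents] <- b
    tss <- sum(Z[, y]^2)                    # z-scored: mean 0
    rss <- sum(fit$residuals^2)
    r2[y] <- 1 - rss / tss
    resid_var[y] <- rss / (n - 1)
  }
  Tm <- solve(diag(length(vars)) - B) - diag(length(vars))
  dimnames(Tm) <- dimnames(B)
  Ind <- Tm - B
  pick <- function(M, to) {
    from <- setdiff(vars, to)
    stats::setNames(M[to, from], paste0(from, "->", to))
  }
  direct <- c(pick(B, "plant"), pick(B, "amf"))
  indirect <- c(pick(Ind, "plant"), pick(Ind, "amf"))
  total <- c(pick(Tm, "plant"), pick(Tm, "amf"))
  structure(list(direct = direct, indirect = indirect, total = total,
                 r_squared = r2, B = B, residual_variance = resid_var,
                 n = n, spec = spec), class = "path_model_result")
}

#' Likelihood-based fit indices for a fitted path model
#'
#' The implied covariance is assembled from the fitted coefficients and
#' residual variances with free exogenous covariances:
#' Sigma = (I - B)^-1 Psi (I - B)^-T.  The maximum-likelihood discrepancy
#' F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p gives chi-square =
#' (n - 1) F; df = p(p+1)/2 - free parameters; RMSEA =
#' sqrt(max(chi2 - df, 0) / (df (n - 1))); TLI compares against the
#' independence baseline.  A saturated model (df = 0) reports chi2 = 0 and
#' RMSEA = 0 with \code{saturated = TRUE} and NA p-value/TLI.
#'
#' @param data The data used for fitting.
#' @param spec The \code{path_spec}.
#' @param fitted The \code{path_model_result} from
#'   \code{\link{fit_path_model}}.
#' @return List with \code{chi2}, \code{df}, \code{p}, \code{rmsea},
#'   \code{tli}, \code{baseline_chi2}, \code{baseline_df},
#'   \code{saturated}.
#' @export
fit_indices <- function(data, spec, fitted) {
  vars <- spec$variables
  Z <- scale(as.matrix(data[, vars]))
  n <- nrow(Z)
  p <- length(vars)
  S <- stats::cov(Z)
  exo <- spec$exogenous
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi[exo, exo] <- S[exo, exo]
  Psi["plant", "plant"] <- fitted$residual_variance["plant"]
  Psi["amf", "amf"] <- fitted$residual_variance["amf"]
  A <- solve(diag(p) - fitted$B)
  Sigma <- A %*% Psi %*% t(A)
  f_ml <- function(Sg) {
    as.numeric(determinant(Sg)$modulus) + sum(diag(S %*% solve(Sg))) -
      as.numeric(determinant(S)$modulus) - p
  }
  nfree <- length(exo) * (length(exo) + 1) / 2 + nrow(spec$edges) + 2
  df <- p * (p + 1) / 2 - nfree
  chi2 <- max((n - 1) * f_ml(Sigma), 0)
  base_df <- p * (p - 1) / 2
  base_chi2 <- max((n - 1) * f_ml(diag(diag(S))), 0)
  if (df <= 0) {
    return(list(chi2 = chi2, df = df, p = NA_real_, rmsea = 0,
                tli = NA_real_, baseline_chi2 = base_chi2,
                baseline_df = base_df, saturated = TRUE))
  }
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  base_ratio <- base_chi2 / base_df
  tli <- if (base_ratio <= 1) NA_real_ else
    (base_ratio - chi2 / df) / (base_ratio - 1)
  list(chi2 = chi2, df = df, p = pval, rmsea = rmsea, tli = tli,
       baseline_chi2 = base_chi2, baseline_df = base_df, saturated = FALSE)
}
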