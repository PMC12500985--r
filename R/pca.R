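#' Principal component analysis on the correlation matrix
#'
#' Columns are standardized to mean 0, SD 1 (the ZX variables) and the
#' correlation matrix is eigen-decomposed with a deterministic symmetric
#' solver. Components are ordered by descending eigenvalue (ties keep
#' original order) and each eigenvector's sign is fixed so its
#' largest-magnitude coefficient is positive, making repeated fits
#' bit-reproducible.
#'
#' Two coefficient conventions are kept side by side: the raw unit-norm
#' eigenvectors, and loadings (eigenvector x sqrt(eigenvalue), the SPSS
#' "component matrix"). Contribution rates are 100 lambda / p for
#' standardized data, where p is the number of indices.
#'
#' @param X genotype-by-index numeric matrix, >= 2 rows and columns, no
#'   constant column.
#' @return object of class `drought_pca`: `eigenvalues`, `eigenvectors`,
#'   `loadings`, `contribution`, `cumulative` (percent), `center`, `scale`,
#'   `n`, `p`.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("input error: PCA needs at least 2 genotypes")
  if (ncol(X) < 2) stop("input error: PCA needs at least 2 indices")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("degenerate-input error: constant column: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  vec <- e$vectors
  # deterministic sign: largest-magnitude coefficient positive per column
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(X), paste0("PC", seq_len(ncol(vec))))
  p <- ncol(X)
  loadings <- sweep(vec, 2, sqrt(pmax(lambda, 0)), `*`)
  contribution <- 100 * lambda / p
  structure(
    list(eigenvalues = lambda, eigenvectors = vec, loadings = loadings,
         contribution = contribution, cumulative = cumsum(contribution),
         center = ctr, scale = scl, n = nrow(X), p = p),
    class = "drought_pca"
  )
}

#' @export
print.drought_pca <- function(x, ...) {
  cat("PCA on the correlation matrix of", x$p, "indices,", x$n, "genotypes\n")
  tab <- data.frame(eigenvalue = round(x$eigenvalues, 3),
                    contribution = round(x$contribution, 3),
                    cumulative = round(x$cumulative, 3))
  print(utils::head(tab, 5))
  if (x$p > 5) cat("... (", x$p, "components )\n")
  invisible(x)
}

#' Component scores F_j
#'
#' F_j for genotype g is the coefficient-weighted sum of its standardized
#' index values, F_j = sum_i a_ij ZX_i, with a_ij taken from the configured
#' convention. Under the raw eigenvector convention score column j has
#' variance lambda_j; under the loadings convention variances are
#' lambda_j^2.
#'
#' @param X genotype-by-index matrix conformable with the fit's
#'   standardization (same columns).
#' @param fit a [fit_pca()] result.
#' @param m number of components to score (default all).
#' @param convention `"loadings"` (SPSS component matrix, default) or
#'   `"eigenvector"` (raw unit-norm).
#' @return genotype x m score matrix, columns `PC1..PCm`.
#' @export
component_scores <- function(X, fit, m = fit$p,
                             convention = c("loadings", "eigenvector")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fit, "drought_pca"))
  if (m < 1 || m > fit$p) {
    stop("parameter error: m must be between 1 and ", fit$p)
  }
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !identical(colnames(X), names(fit$center))) {
    X <- X[, names(fit$center), drop = FALSE]
  }
  Z <- scale(X, center = fit$center, scale = fit$scale)
  A <- switch(convention, loadings = fit$loadings,
              eigenvector = fit$eigenvectors)
  Z %*% A[, seq_len(m), drop = FALSE]
}

#' Number of components to retain
#'
#' @param fit a [fit_pca()] result.
#' @param rule `"fixed_m"` (default, returns `m`), `"kaiser"` (count of
#'   eigenvalues > 1) or `"cumulative_threshold"` (smallest m whose
#'   cumulative contribution reaches `threshold` percent).
#' @param m retained count for the fixed rule (default 3).
#' @param threshold cumulative contribution threshold in (0, 100\].
#' @return integer component count.
#' @export
retain_components <- function(fit, rule = c("fixed_m", "kaiser",
                                            "cumulative_threshold"),
                              m = 3, threshold = 85) {
  rule <- match.arg(rule)
  lambda <- if (inherits(fit, "drought_pca")) fit$eigenvalues else fit
  p <- length(lambda)
  switch(rule,
    fixed_m = {
      if (m < 1 || m > p) stop("parameter error: m out of range")
      as.integer(m)
    },
    kaiser = as.integer(sum(lambda > 1)),
    cumulative_threshold = {
      if (threshold <= 0 || threshold > 100) {
        stop("parameter error: threshold must be in (0, 100]")
      }
      cum <- 100 * cumsum(lambda) / sum(lambda)
      as.integer(which(cum >= threshold - 1e-12)[1])
    })
}

#' Serialize a PCA fit to a JSON report
#'
#' Writes eigenvalues, the contribution-rate table and both coefficient
#' matrices.
#'
#' @param fit a [fit_pca()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
pca_report <- function(fit, path) {
  stopifnot(inherits(fit, "drought_pca"))
  obj <- list(
    eigenvalues = fit$eigenvalues,
    contribution_rate_pct = fit$contribution,
    cumulative_contribution_pct = fit$cumulative,
    index = rownames(fit$eigenvectors),
    eigenvectors = as.data.frame(fit$eigenvectors, row.names = FALSE),
    loadings = as.data.frame(fit$loadings, row.names = FALSE),
    n_genotypes = fit$n, n_indices = fit$p
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
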