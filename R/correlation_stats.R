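#' Pearson correlation matrix with two-tailed significance
#'
#' Pairwise Pearson r over the columns of an observation-by-variable
#' matrix, with two-tailed p-values from the exact t reference
#' distribution, t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom
#' (appropriate for the small panels this package targets), and star
#' annotation at the conventional thresholds (* p < 0.05, ** p < 0.01).
#' Constant variables yield undefined correlations: their pairs are
#' flagged `NA` with a warning rather than raising an error.
#'
#' @param X observation x variable numeric matrix or data.frame (n >= 3).
#' @return object of class `correlation_result`: `r`, `p`, `stars`
#'   (character matrix), `n`.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("correlation needs at least 3 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant variable(s), correlations undefined: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.finite(tstat)] <- 0          # |r| = 1 exactly
  diag(p) <- ifelse(sds == 0, NA_real_, 0)
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Pearson correlations over", x$n, "observations\n")
  print(format_correlation(x), quote = FALSE)
  invisible(x)
}

#' Lower-triangle correlation report with stars
#'
#' Formats a [pearson_matrix()] result in the conventional table layout:
#' lower triangle only, coefficients rounded to `digits` with significance
#' stars appended, unit diagonal, blanks above the diagonal.
#'
#' @param cr a `correlation_result`.
#' @param digits rounding (default 3).
#' @return character matrix.
#' @export
format_correlation <- function(cr, digits = 3) {
  stopifnot(inherits(cr, "correlation_result"))
  r <- cr$r
  out <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(i)) {
      out[i, j] <- if (is.na(r[i, j])) "NA" else
        paste0(formatC(round(r[i, j], digits), format = "f", digits = digits),
               if (i != j) cr$stars[i, j] else "")
    }
  }
  out
}

#' Correlate a comprehensive score with covariates
#'
#' Helper for score-vs-covariate tables (e.g. D value against ploidy,
#' petal type and physiological indices). Non-numeric covariates must be
#' pre-coded by the caller; the default coding used in this package's
#' examples is ploidy as the chromosome multiplier (2 or 3) and petal type
#' as single = 1 / double = 2.
#'
#' @param score numeric vector (e.g. the D value per genotype).
#' @param covariates data.frame or matrix of numeric covariates, one row
#'   per genotype.
#' @param score_name label for the score row (default `"D"`).
#' @return data.frame with one row per covariate: `covariate`, `r`, `p`,
#'   `stars`.
#' @export
correlate_with_score <- function(score, covariates, score_name = "D") {
  M <- cbind(score = score, as.matrix(covariates))
  colnames(M)[1] <- score_name
  cr <- pearson_matrix(M)
  data.frame(covariate = colnames(M)[-1],
             r = cr$r[1, -1], p = cr$p[1, -1], stars = cr$stars[1, -1],
             row.names = NULL, stringsAsFactors = FALSE)
}
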