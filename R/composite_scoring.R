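#' Eigenvalue-proportion component weights
#'
#' W_j = lambda_j / p under the `"total_variance_p"` denominator (the
#' proportion of total standardized variance carried by component j, i.e.
#' its contribution rate / 100), or W_j = lambda_j / sum(lambda_1..m) under
#' `"extracted_sum"` (weights sum to 1 over the retained components).
#'
#' For a 13-index panel with leading eigenvalues (4.278, 3.109, 2.241) the
#' total-variance denominator gives the familiar (0.329, 0.239, 0.172).
#'
#' @param eigenvalues full eigenvalue vector (descending), all >= 0.
#' @param m retained component count.
#' @param denominator `"total_variance_p"` (default) or `"extracted_sum"`.
#' @param p total index count; defaults to `length(eigenvalues)` and is
#'   only needed when a truncated eigenvalue vector is supplied.
#' @return numeric weight vector of length `m`.
#' @export
component_weights <- function(eigenvalues, m,
                              denominator = c("total_variance_p",
                                              "extracted_sum"),
                              p = length(eigenvalues)) {
  denominator <- match.arg(denominator)
  if (m < 1 || m > length(eigenvalues)) {
    stop("parameter error: m out of range")
  }
  if (any(eigenvalues < -1e-8)) stop("eigenvalues must be non-negative")
  lam <- eigenvalues[seq_len(m)]
  den <- switch(denominator, total_variance_p = p, extracted_sum = sum(lam))
  if (den <= 0) stop("degenerate error: zero weight denominator")
  lam / den
}

#' Composite F score
#'
#' The eigenvalue-weighted average of a genotype's component scores,
#' F = sum(lambda_j F_j) / sum(lambda_j), collapsing the retained
#' components into one overall score.
#'
#' @param scores genotype x m component-score matrix.
#' @param eigenvalues eigenvalues of the retained components (length m).
#' @return numeric vector of composite F values, one per genotype.
#' @export
composite_f <- function(scores, eigenvalues) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(eigenvalues)) {
    stop("parameter error: need one eigenvalue per score column")
  }
  if (sum(eigenvalues) == 0) stop("degenerate error: eigenvalues sum to zero")
  drop(scores %*% eigenvalues) / sum(eigenvalues)
}

#' Comprehensive D values and genotype ranking
#'
#' Each component-score column is membership-transformed across genotypes
#' (positive direction: a higher component score indicates stronger
#' resistance), and the comprehensive evaluation value is the weighted sum
#' D_g = sum_j u_gj W_j. Genotypes are ranked by descending D; exact ties
#' keep input order and are flagged.
#'
#' @param scores genotype x m component-score matrix (rownames = genotype
#'   IDs; synthesized as G1..Gn when absent).
#' @param weights component weights W_1..W_m (>= 0, not all zero).
#' @param degenerate passed to [membership_transform()]; the default errors
#'   on a constant score column, `"mid"` substitutes 0.5 (useful when
#'   trailing components carry no variance).
#' @return data.frame of class `score_table`: `genotype`, `F1..Fm`,
#'   `mu1..mum`, `D`, `rank`, `tied`; the weights are kept in
#'   `attr(, "weights")`.
#' @export
d_values <- function(scores, weights, degenerate = c("error", "mid")) {
  degenerate <- match.arg(degenerate)
  scores <- as.matrix(scores)
  G <- nrow(scores); m <- ncol(scores)
  if (G < 2) stop("need at least 2 genotypes")
  if (length(weights) != m) stop("parameter error: one weight per component")
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  genos <- rownames(scores)
  if (is.null(genos)) genos <- paste0("G", seq_len(G))
  mu <- scores
  for (j in seq_len(m)) {
    mu[, j] <- membership_transform(scores[, j], "positive", degenerate)
  }
  D <- drop(mu %*% weights)
  ord <- order(-D, seq_len(G))   # ties broken by input order
  rank <- integer(G); rank[ord] <- seq_len(G)
  tied <- duplicated(D) | duplicated(D, fromLast = TRUE)
  out <- data.frame(genotype = genos, stringsAsFactors = FALSE)
  for (j in seq_len(m)) out[[paste0("F", j)]] <- scores[, j]
  for (j in seq_len(m)) out[[paste0("mu", j)]] <- mu[, j]
  out$D <- D
  out$rank <- rank
  out$tied <- tied
  rownames(out) <- NULL
  attr(out, "weights") <- weights
  class(out) <- c("score_table", "data.frame")
  out
}

#' Write a score table to CSV
#'
#' Mirrors the standard report layout: F columns, membership columns, D and
#' rank, rounded to `digits`, followed by a weights footer row. A
#' full-precision companion file (suffix `_raw`) is written alongside.
#'
#' @param st a [d_values()] score table.
#' @param path output CSV path.
#' @param digits rounding for the report (default 3).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(st, path, digits = 3) {
  stopifnot(inherits(st, "score_table"))
  w <- attr(st, "weights")
  num <- vapply(st, is.numeric, TRUE) & names(st) != "rank"
  rep_df <- st
  rep_df[num] <- lapply(rep_df[num], round, digits = digits)
  footer <- rep_df[1, ]
  footer[] <- NA
  footer$genotype <- "Weights"
  fcols <- paste0("F", seq_along(w))
  footer[fcols] <- round(w, digits)
  utils::write.csv(rbind(rep_df, footer), path, row.names = FALSE, na = "")
  raw_path <- sub("(\\.[^.]+)?$", "_raw\\1", path)
  utils::write.csv(st, raw_path, row.names = FALSE)
  invisible(path)
}
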