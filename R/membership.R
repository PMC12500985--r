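#' Fuzzy membership-function transform
#'
#' Min-max ("subordinate function") normalization of a value vector across
#' genotypes onto \[0, 1\]:
#'
#'   positive direction: u(x) = (x - min) / (max - min)
#'   negative direction: u(x) = 1 - (x - min) / (max - min)
#'
#' so an index positively associated with resistance maps its maximum to 1,
#' while a damage marker (negative direction) maps its minimum to 1. The
#' transform is invariant under positive affine rescaling of `x`, which
#' makes everything downstream independent of raw units.
#'
#' A degenerate (constant) vector is an error by default, because silently
#' emitting a constant would corrupt the PCA input; `degenerate = "mid"`
#' instead returns 0.5 for every genotype with a warning. Degeneracy is
#' judged relative to the magnitude of the data so that vectors constant up
#' to floating-point dust are caught too.
#'
#' @param x numeric vector (length >= 2, finite).
#' @param direction `"positive"` or `"negative"`.
#' @param degenerate `"error"` (default) or `"mid"`.
#' @return numeric vector in \[0, 1\], names preserved.
#' @export
#' @examples
#' membership_transform(c(2, 8, 5), "positive")   # 0, 1, 0.5
#' membership_transform(c(2, 8, 5), "negative")   # 1, 0, 0.5
membership_transform <- function(x, direction = c("positive", "negative"),
                                 degenerate = c("error", "mid")) {
  direction <- match.arg(direction)
  degenerate <- match.arg(degenerate)
  if (length(x) < 2) stop("membership transform needs at least 2 values")
  if (any(!is.finite(x))) stop("membership transform needs finite values")
  rng <- max(x) - min(x)
  if (rng <= 1e-10 * max(abs(max(x)), abs(min(x)), 1)) {
    if (degenerate == "error") {
      stop("degenerate-range error: all values effectively equal")
    }
    warning("degenerate range: returning constant membership 0.5")
    u <- rep(0.5, length(x))
    names(u) <- names(x)
    return(u)
  }
  u <- (x - min(x)) / rng
  if (direction == "negative") u <- 1 - u
  u
}

#' Membership matrix for a genotype-by-index value matrix
#'
#' Applies [membership_transform()] column-wise using the per-index
#' direction from an [index_spec()].
#'
#' @param X genotype-by-index numeric matrix (column names are indices).
#' @param spec an [index_spec()] declaring a direction for every column.
#' @param degenerate passed to [membership_transform()].
#' @return matrix of membership values in \[0, 1\], same dimnames as `X`.
#' @export
membership_matrix <- function(X, spec, degenerate = c("error", "mid")) {
  degenerate <- match.arg(degenerate)
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  miss <- setdiff(colnames(X), spec$index)
  if (length(miss)) {
    stop("spec error: no direction declared for index: ",
         paste(miss, collapse = ", "))
  }
  dirs <- spec$direction[match(colnames(X), spec$index)]
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- tryCatch(
      membership_transform(X[, j], dirs[j], degenerate),
      error = function(e) stop("index '", colnames(X)[j], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  out
}
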