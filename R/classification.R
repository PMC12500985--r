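#' Agglomerative clustering of genotypes into resistance groups
#'
#' Euclidean-distance agglomerative clustering with furthest-neighbour
#' (complete) linkage by default, or between-groups average linkage.
#' Merge heights are additionally reported on the SPSS-style 0-25 rescaled
#' dendrogram scale (min-max mapped so the first merge sits at 0 and the
#' final merge at 25), and the tree can be cut either at a fixed number of
#' groups `k` or at a rescaled-height threshold.
#'
#' Group labels are renumbered so that group 1 contains the first genotype
#' in panel order, etc. Ties in merge order are resolved by the underlying
#' deterministic [stats::hclust()] agglomeration; for continuous feature
#' data exact ties are non-generic.
#'
#' @param X genotype-by-feature numeric matrix (rownames = genotype IDs).
#' @param linkage `"complete"` (default) or `"average"`.
#' @param k number of groups to cut (default 3); ignored when
#'   `h_rescaled` is given.
#' @param h_rescaled optional cut threshold on the 0-25 rescaled scale.
#' @return object of class `cluster_grouping`: `hclust` (raw heights),
#'   `merge`, `height_raw`, `height_rescaled`, `labels` (named integer
#'   vector), `k`, `linkage`.
#' @export
cluster_genotypes <- function(X, linkage = c("complete", "average"),
                              k = 3, h_rescaled = NULL) {
  linkage <- match.arg(linkage)
  X <- as.matrix(X)
  G <- nrow(X)
  if (G < 2) stop("clustering needs at least 2 genotypes")
  if (any(!is.finite(X))) stop("clustering needs finite features")
  if (is.null(rownames(X))) rownames(X) <- paste0("G", seq_len(G))
  hc <- stats::hclust(stats::dist(X, method = "euclidean"), method = linkage)
  h <- hc$height
  hr <- if (length(h) == 1) {
    25
  } else if (max(h) == min(h)) {
    rep(25, length(h))
  } else {
    25 * (h - min(h)) / (max(h) - min(h))
  }
  if (!is.null(h_rescaled)) {
    if (h_rescaled < 0 || h_rescaled > 25) {
      stop("parameter error: rescaled cut height must be in [0, 25]")
    }
    # invert the rescaling to a raw height and cut there
    h_raw <- if (length(h) == 1) h else min(h) + h_rescaled / 25 * (max(h) - min(h))
    labels <- stats::cutree(hc, h = h_raw)
    k <- length(unique(labels))
  } else {
    if (k < 1 || k > G) stop("parameter error: k must be in 1..", G)
    labels <- stats::cutree(hc, k = k)
  }
  # renumber groups by first appearance in input order
  first <- match(unique(labels), labels)
  relab <- match(labels, labels[sort(first)])
  names(relab) <- rownames(X)
  structure(
    list(hclust = hc, merge = hc$merge, height_raw = h,
         height_rescaled = hr, labels = relab, k = as.integer(k),
         linkage = linkage),
    class = "cluster_grouping"
  )
}

#' @export
print.cluster_grouping <- function(x, ...) {
  cat("Agglomerative clustering (", x$linkage, " linkage): ",
      length(x$labels), " genotypes in ", x$k, " groups\n", sep = "")
  print(split(names(x$labels), x$labels))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Leaf names are the genotype IDs; branch lengths come from the 0-25
#' rescaled merge heights so the file mirrors the printed dendrogram axis.
#'
#' @param cg a [cluster_genotypes()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(cg, path) {
  stopifnot(inherits(cg, "cluster_grouping"))
  hc <- cg$hclust
  hc$height <- cg$height_rescaled
  # cumulative heights must be non-decreasing for as.phylo; complete and
  # average linkage are monotone so the rescaled heights are too
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Row-standardized matrix for heatmap display
#'
#' Transposes a genotype-by-index matrix to index-by-genotype, scales each
#' index row to mean 0, SD 1 across genotypes (constant rows become zeros
#' with a warning), and orders rows and columns by complete-linkage
#' clustering of the standardized matrix.
#'
#' @param X genotype-by-index numeric matrix.
#' @return list: `matrix` (index x genotype, standardized), `row_order`
#'   (index names), `col_order` (genotype names).
#' @export
heatmap_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("G", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  M <- t(X)  # index rows, genotype columns
  sds <- apply(M, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant index row(s) set to zero: ",
            paste(rownames(M)[sds == 0], collapse = ", "))
  }
  Z <- M
  for (i in seq_len(nrow(M))) {
    Z[i, ] <- if (sds[i] == 0) 0 else (M[i, ] - mean(M[i, ])) / sds[i]
  }
  row_hc <- stats::hclust(stats::dist(Z), method = "complete")
  col_hc <- stats::hclust(stats::dist(t(Z)), method = "complete")
  list(matrix = Z,
       row_order = rownames(Z)[row_hc$order],
       col_order = colnames(Z)[col_hc$order])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expectation under random
#' labeling. Used to check recovery of planted groups on synthetic panels.
#'
#' @param a,b label vectors of equal length (any types coercible to factor).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
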