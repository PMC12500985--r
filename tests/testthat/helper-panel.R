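# shared builders and independent oracles used across test files

# tiny balanced tidy panel: values are deterministic from the cell key so
# round-trip comparisons are exact
make_tidy_df <- function(genotypes = c("A", "B"), indices = "RWC",
                         conditions = c("control", "treatment"),
                         replicates = 3) {
  g <- expand.grid(replicate = seq_len(replicates), condition = conditions,
                   index = indices, genotype = genotypes,
                   stringsAsFactors = FALSE)
  g <- g[, c("genotype", "index", "condition", "replicate")]
  g$value <- 10 * match(g$genotype, genotypes) +
    match(g$index, indices) +
    0.5 * (g$condition == "treatment") + 0.01 * g$replicate
  g
}

# trait_matrix built from the bundled pigment table (means as single reps)
pigment_panel <- function() {
  df <- hemerocallis_pigments()
  df$replicate <- 1L
  df$value <- df$mean
  spec <- index_spec(c("Chl", "Chl_a", "Chl_b", "Chl_ab", "Car"))
  trait_matrix(df[, c("genotype", "index", "condition", "replicate", "value")],
               spec = spec)
}

table6_scores <- function() {
  st <- hemerocallis_scores()
  F <- as.matrix(st[, c("F1", "F2", "F3")])
  rownames(F) <- st$genotype
  F
}

# exhaustive complete-linkage agglomeration: at every step scan all cluster
# pairs and merge the one with the smallest maximum pairwise distance
brute_force_complete_linkage <- function(X) {
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  merges <- vector("list", nrow(X) - 1)
  for (k in seq_len(nrow(X) - 1)) {
    bestd <- Inf; best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- max(D[clusters[[j]], clusters[[i]]])
        if (d < bestd) { bestd <- d; best <- c(j, i) }
      }
    }
    members <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[k]] <- list(members = members, height = bestd)
    clusters[[best[1]]] <- members
    clusters[[best[2]]] <- NULL
  }
  merges
}

# member sets + heights along an hclust merge sequence, same shape as the
# brute-force oracle output
hclust_merges <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    members <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
    sets[[k]] <- members
    out[[k]] <- list(members = members, height = hc$height[k])
  }
  out
}
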