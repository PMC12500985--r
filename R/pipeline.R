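#' Pipeline configuration
#'
#' Collects every knob of the end-to-end evaluation in one validated
#' object. All enumerated fields are checked against their documented
#' values, and the config round-trips losslessly through JSON (and YAML,
#' when the \pkg{yaml} package is installed).
#'
#' @param input path to a tidy trait CSV (see [read_trait_table()]), or
#'   `NULL` when a [trait_matrix()] is passed to [run_pipeline()] directly.
#' @param index_spec path to an index-spec file, or `NULL` for
#'   [default_index_spec()].
#' @param out_dir output directory for the report bundle.
#' @param pca_input which genotype x index matrix feeds the membership +
#'   PCA stages: `"drought_coefficient"` (default; treatment/control mean
#'   ratio), `"treatment_mean"`, or `"percent_change"`.
#' @param convention component-coefficient convention for scores,
#'   `"loadings"` (default) or `"eigenvector"`.
#' @param retention component retention rule (`"fixed_m"` default,
#'   `"kaiser"`, `"cumulative_threshold"`).
#' @param m retained components for the fixed rule (default 3).
#' @param threshold cumulative-contribution threshold (percent).
#' @param weight_denominator `"total_variance_p"` (default) or
#'   `"extracted_sum"`, see [component_weights()].
#' @param linkage clustering linkage, `"complete"` (default) or
#'   `"average"`.
#' @param cluster_on features for clustering: `"component_scores"`
#'   (default), `"composite_f"`, or `"d_value"`.
#' @param k number of resistance groups (default 3).
#' @param h_rescaled optional rescaled-height cut overriding `k`.
#' @param digits report rounding (scores; percentages use `digits - 1`).
#' @param seed integer seed recorded in the manifest (used only by
#'   synthetic runs).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, index_spec = NULL,
                            out_dir = ".",
                            pca_input = c("drought_coefficient",
                                          "treatment_mean",
                                          "percent_change"),
                            convention = c("loadings", "eigenvector"),
                            retention = c("fixed_m", "kaiser",
                                          "cumulative_threshold"),
                            m = 3, threshold = 85,
                            weight_denominator = c("total_variance_p",
                                                   "extracted_sum"),
                            linkage = c("complete", "average"),
                            cluster_on = c("component_scores",
                                           "composite_f", "d_value"),
                            k = 3, h_rescaled = NULL,
                            digits = 3, seed = 1L) {
  structure(
    list(input = input, index_spec = index_spec, out_dir = out_dir,
         pca_input = match.arg(pca_input),
         convention = match.arg(convention),
         retention = match.arg(retention), m = m, threshold = threshold,
         weight_denominator = match.arg(weight_denominator),
         linkage = match.arg(linkage), cluster_on = match.arg(cluster_on),
         k = k, h_rescaled = h_rescaled, digits = digits,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline config (JSON or YAML)
#'
#' @param path config file path (`.json`, or `.yml`/`.yaml` with the
#'   optional \pkg{yaml} package).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, lst)
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full drought-resistance evaluation pipeline
#'
#' tidy panel -> response statistics -> membership matrix -> PCA ->
#' component scores, weights, composite F and D values -> resistance
#' groups -> correlation report. Writes the complete bundle to
#' `cfg$out_dir`: `response.csv`, `pca.json`, `scores.csv` (+ raw
#' companion), `groups.csv`, `dendrogram.nwk`, `correlations.csv` and a
#' `manifest.json` recording the config hash and package version. Identical
#' config and inputs produce byte-identical outputs.
#'
#' Components beyond the informative ones can have (near-)constant score
#' columns on strongly structured data; the scoring stage substitutes the
#' neutral membership 0.5 for those instead of aborting, and says so in the
#' manifest.
#'
#' @param cfg a [pipeline_config()].
#' @param tm optional in-memory [trait_matrix()]; overrides `cfg$input`.
#' @return invisible list with every intermediate object and output path.
#' @export
run_pipeline <- function(cfg, tm = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- stage("index_spec", {
    if (is.null(cfg$index_spec)) default_index_spec()
    else read_index_spec(cfg$index_spec)
  })
  tm <- stage("load", {
    if (!is.null(tm)) tm else read_trait_table(cfg$input, spec = spec)
  })
  spec <- tm$spec

  resp <- stage("respond", response_table(tm))
  resp_path <- file.path(cfg$out_dir, "response.csv")
  utils::write.csv(resp, resp_path, row.names = FALSE)

  X <- stage("pca_input", switch(cfg$pca_input,
    drought_coefficient = drought_coefficient_matrix(tm),
    treatment_mean = means_matrix(tm, "treatment"),
    percent_change = {
      M <- matrix(resp$pct_change, length(tm$genotypes), length(tm$indices),
                  byrow = TRUE, dimnames = list(tm$genotypes, tm$indices))
      M
    }))
  U <- stage("membership", membership_matrix(X, spec))

  fit <- stage("pca", fit_pca(U))
  m <- stage("retain", retain_components(fit, cfg$retention, m = cfg$m,
                                         threshold = cfg$threshold))
  scores <- stage("scores", component_scores(U, fit, m = m,
                                             convention = cfg$convention))
  pca_path <- file.path(cfg$out_dir, "pca.json")
  pca_report(fit, pca_path)

  w <- stage("weights", component_weights(fit$eigenvalues, m,
                                          denominator = cfg$weight_denominator))
  f_comp <- stage("composite_f", composite_f(scores, fit$eigenvalues[seq_len(m)]))
  degenerate_cols <- apply(scores, 2, function(v) {
    diff(range(v)) <= 1e-10 * max(abs(range(v)), 1)
  })
  st <- stage("score", suppressWarnings(
    d_values(scores, w, degenerate = if (any(degenerate_cols)) "mid" else "error")
  ))
  st$composite_F <- f_comp
  scores_path <- file.path(cfg$out_dir, "scores.csv")
  write_score_table(st, scores_path, digits = cfg$digits)

  feat <- stage("cluster_features", switch(cfg$cluster_on,
    component_scores = scores,
    composite_f = matrix(f_comp, ncol = 1,
                         dimnames = list(rownames(scores), "F")),
    d_value = matrix(st$D, ncol = 1, dimnames = list(st$genotype, "D"))))
  cg <- stage("classify", cluster_genotypes(feat, linkage = cfg$linkage,
                                            k = cfg$k,
                                            h_rescaled = cfg$h_rescaled))
  groups_path <- file.path(cfg$out_dir, "groups.csv")
  utils::write.csv(data.frame(genotype = names(cg$labels),
                              group = unname(cg$labels),
                              D = st$D[match(names(cg$labels), st$genotype)],
                              rank = st$rank[match(names(cg$labels),
                                                   st$genotype)]),
                   groups_path, row.names = FALSE)
  nwk_path <- file.path(cfg$out_dir, "dendrogram.nwk")
  write_dendrogram_newick(cg, nwk_path)

  corr <- stage("correlate", pearson_matrix(U))
  corr_path <- file.path(cfg$out_dir, "correlations.csv")
  utils::write.csv(format_correlation(corr, digits = cfg$digits),
                   corr_path)

  cfg_path <- file.path(cfg$out_dir, "config.json")
  write_pipeline_config(cfg, cfg_path)
  # hash the analytic settings only: where the bundle lands is not part of
  # the analysis identity
  cfg_hash <- unclass(cfg)
  cfg_hash$out_dir <- NULL
  hash_file <- tempfile()
  on.exit(unlink(hash_file), add = TRUE)
  jsonlite::write_json(cfg_hash, hash_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "droughtscore",
    version = as.character(utils::packageVersion("droughtscore")),
    config_md5 = unname(tools::md5sum(hash_file)),
    n_genotypes = length(tm$genotypes), n_indices = length(tm$indices),
    retained_components = m,
    degenerate_score_columns = names(degenerate_cols)[degenerate_cols]
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(traits = tm, response = resp, pca_input = X,
                 membership = U, pca = fit, m = m, scores = scores,
                 weights = w, composite_F = f_comp, score_table = st,
                 grouping = cg, correlations = corr,
                 paths = c(response = resp_path, pca = pca_path,
                           scores = scores_path, groups = groups_path,
                           dendrogram = nwk_path, correlations = corr_path,
                           config = cfg_path, manifest = manifest_path)))
}
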