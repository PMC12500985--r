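#' Bundled daylily reference-panel tables
#'
#' Published summary tables from a comprehensive drought-resistance
#' evaluation of 25 wild daylily (*Hemerocallis fulva*) genotypes
#' (S1..S25) phenotyped under full vs deficit irrigation, shipped as
#' plain-text fixtures:
#'
#' * `hemerocallis_scores()` — per-genotype component scores F1..F3 on the
#'   three retained principal components, the reported membership values
#'   mu1..mu3, comprehensive D value and rank.
#' * `hemerocallis_eigenvalues()` — all 13 eigenvalues with contribution
#'   and cumulative contribution rates (percent).
#' * `hemerocallis_loadings()` — the 13-index x 3-component coefficient
#'   matrix.
#' * `hemerocallis_pigments()` — control/treatment pigment means (+/- SD):
#'   total chlorophyll, Chl a, Chl b, the Chl a/b ratio and carotenoids,
#'   in mg per g fresh weight (ratio unitless).
#'
#' These fixtures exercise everything downstream of a fitted PCA: the raw
#' per-replicate data behind the upstream fit are not published, so the
#' PCA stage itself is validated on synthetic panels instead.
#'
#' @return a data.frame (see above).
#' @name reference_panel
NULL

ds_extdata <- function(file) {
  path <- system.file("extdata", file, package = "droughtscore")
  if (path == "") stop("fixture not found: ", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_panel
#' @export
hemerocallis_scores <- function() ds_extdata("hemerocallis_f_values.csv")

#' @rdname reference_panel
#' @export
hemerocallis_eigenvalues <- function() ds_extdata("hemerocallis_eigenvalues.csv")

#' @rdname reference_panel
#' @export
hemerocallis_loadings <- function() ds_extdata("hemerocallis_loadings.csv")

#' @rdname reference_panel
#' @export
hemerocallis_pigments <- function() ds_extdata("hemerocallis_pigment_means.csv")
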