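#' Percent change of a trait under treatment
#'
#' Signed percent change 100 (treatment - control) / control. Invariant
#' under a common positive rescaling of both means, so unit choices cancel.
#'
#' @param control,treatment cell means (control must be nonzero).
#' @return percent change, vectorized.
#' @export
#' @examples
#' percent_change(1.144, 1.668)  # +45.8%
percent_change <- function(control, treatment) {
  if (any(control == 0)) stop("domain error: control mean is zero")
  100 * (treatment - control) / control
}

#' Drought coefficient (treatment/control ratio)
#'
#' The unitless ratio of the treatment mean to the control mean for one
#' genotype and index; values below 1 indicate suppression under deficit
#' irrigation.
#'
#' @inheritParams percent_change
#' @return treatment / control, vectorized.
#' @export
drought_coefficient <- function(control, treatment) {
  if (any(control == 0)) stop("domain error: control mean is zero")
  treatment / control
}

#' Paired two-tailed t-test with table-style significance letters
#'
#' Classical paired t on the replicate differences, replicates paired by
#' position (replicate ID order). Zero-variance differences are handled
#' explicitly: all-zero differences give t = 0, p = 1; constant nonzero
#' differences are an infinite-t limit reported with p at the smallest
#' representable positive double and a warning.
#'
#' @param control,treatment equal-length replicate vectors, n >= 2.
#' @param alpha significance level for the flag and letters (default 0.05).
#' @return list with `t`, `df`, `p`, `significant`, and `letters` (c(control
#'   letter, treatment letter); same letter means not significant, as in
#'   mean +/- SD summary tables).
#' @export
paired_t_test <- function(control, treatment, alpha = 0.05) {
  if (length(control) != length(treatment)) {
    stop("paired test needs equal-length replicate vectors")
  }
  n <- length(control)
  if (n < 2) stop("insufficient data: paired t-test needs n >= 2")
  d <- treatment - control
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(d)) * Inf
      p <- .Machine$double.xmin
      warning("zero variance of differences with nonzero mean; ",
              "p reported at the representable lower limit")
    }
  } else {
    t <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  sig <- p < alpha
  list(t = t, df = n - 1, p = p, significant = sig,
       letters = if (sig) c("a", "b") else c("a", "a"))
}

#' Control-vs-treatment response table
#'
#' Per (genotype, index): control and treatment means, signed percent
#' change, drought coefficient (treatment/control), and a paired two-tailed
#' t-test over replicates with significance letters. Cells with a single
#' replicate get NA test results. No multiple-testing correction is applied
#' by default, mirroring the per-cell presentation of phenotyping tables; a
#' Benjamini-Hochberg adjusted column can be requested.
#'
#' @param tm a [trait_matrix()] with both conditions.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"` to append an adjusted p
#'   column (`p_adj`) and flag significance on it.
#' @return data.frame of class `response_table`.
#' @export
response_table <- function(tm, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(tm, "trait_matrix"))
  adjust <- match.arg(adjust)
  if (!all(c("control", "treatment") %in% tm$conditions)) {
    stop("response table needs both control and treatment conditions")
  }
  d <- tm$data
  grid <- expand.grid(index = tm$indices, genotype = tm$genotypes,
                      stringsAsFactors = FALSE)[, c("genotype", "index")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$genotype[i]; ix <- grid$index[i]
    ctl <- d$value[d$genotype == g & d$index == ix & d$condition == "control"]
    trt <- d$value[d$genotype == g & d$index == ix & d$condition == "treatment"]
    ctl <- ctl[order(d$replicate[d$genotype == g & d$index == ix &
                                   d$condition == "control"])]
    trt <- trt[order(d$replicate[d$genotype == g & d$index == ix &
                                   d$condition == "treatment"])]
    cm <- mean(ctl); tmn <- mean(trt)
    tt <- if (length(ctl) >= 2 && length(ctl) == length(trt)) {
      paired_t_test(ctl, trt, alpha = alpha)
    } else {
      list(t = NA_real_, p = NA_real_, significant = NA)
    }
    data.frame(genotype = g, index = ix,
               control_mean = cm, treatment_mean = tmn,
               pct_change = percent_change(cm, tmn),
               drought_coef = drought_coefficient(cm, tmn),
               t = tt$t, p = tt$p, significant = tt$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
  }
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  out
}

#' Drought-coefficient matrix for a panel
#'
#' Genotype-by-index matrix of treatment/control mean ratios, the default
#' input to the membership + PCA stages.
#'
#' @param tm a [trait_matrix()].
#' @return numeric matrix, genotypes x indices in panel order.
#' @export
drought_coefficient_matrix <- function(tm) {
  means_matrix(tm, "treatment") / means_matrix(tm, "control")
}
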