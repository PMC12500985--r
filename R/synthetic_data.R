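#' Configuration for a synthetic drought-phenotyping panel
#'
#' Describes a replicated control/treatment genotype panel with three
#' planted resistance groups (high / moderate / low). Each genotype gets a
#' latent resistance score: its group centre plus a clipped Gaussian
#' jitter. Per-index treatment effects are declared per group (as signed
#' fractions of the control baseline) and interpolated piecewise-linearly
#' against the latent score, so the planted ranking is strictly monotone
#' and, in the noise-free limit, exactly recoverable. Effects must respect
#' the index direction: for positive-direction indices the high-resistance
#' group keeps the largest (least negative) effect, for damage markers
#' (negative direction) it keeps the smallest increase.
#'
#' Defaults emulate a realistic endpoint design: 25 genotypes (6/7/12 split
#' across groups), 13 indices with field-plausible baselines, 3 replicates,
#' multiplicative replicate noise with a 2% coefficient of variation, and
#' ~10% genotype-level variation in control baselines.
#'
#' @param G genotype count.
#' @param group_props named proportions for high/moderate/low groups
#'   (sum to 1).
#' @param spec an [index_spec()]; defaults to [default_index_spec()].
#' @param baseline named control baseline mean per index.
#' @param baseline_cv genotype-level CV of control baselines.
#' @param effects index x group matrix of signed treatment effects
#'   (fraction of baseline), columns `high`, `moderate`, `low`.
#' @param group_centers latent-score centres per group.
#' @param jitter_sd SD of the latent-score jitter (clipped at +/- 0.15 so
#'   group labels always agree with latent-score order).
#' @param noise_cv replicate-level multiplicative noise CV (>= 0).
#' @param replicates replicate count per cell (>= 1).
#' @param seed integer seed; required, there is no silent global default.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(G = 25,
                             group_props = c(high = 0.24, moderate = 0.28,
                                             low = 0.48),
                             spec = default_index_spec(),
                             baseline = NULL,
                             baseline_cv = 0.10,
                             effects = NULL,
                             group_centers = c(high = 0.90, moderate = 0.55,
                                               low = 0.20),
                             jitter_sd = 0.04,
                             noise_cv = 0.02,
                             replicates = 3,
                             seed) {
  if (missing(seed)) stop("config error: a seed is required")
  if (G < 3) stop("config error: need at least 3 genotypes")
  if (abs(sum(group_props) - 1) > 1e-8 || any(group_props < 0)) {
    stop("config error: group proportions must be non-negative and sum to 1")
  }
  if (!identical(names(group_props), c("high", "moderate", "low"))) {
    stop("config error: group_props must be named high, moderate, low")
  }
  if (replicates < 1) stop("config error: replicates must be >= 1")
  if (noise_cv < 0) stop("config error: noise CV must be >= 0")
  if (is.null(baseline)) baseline <- default_baseline()[spec$index]
  if (is.null(effects)) effects <- default_effects()[spec$index, , drop = FALSE]
  if (!all(spec$index %in% names(baseline))) {
    stop("config error: baseline must name every index in the spec")
  }
  if (!all(spec$index %in% rownames(effects)) ||
      !identical(colnames(effects), c("high", "moderate", "low"))) {
    stop("config error: effects must be an index x (high,moderate,low) matrix")
  }
  # monotone effects across groups, respecting index direction
  for (i in seq_len(nrow(spec))) {
    e <- effects[spec$index[i], ]
    ok <- if (spec$direction[i] == "positive") {
      e["high"] >= e["moderate"] && e["moderate"] >= e["low"]
    } else {
      e["high"] <= e["moderate"] && e["moderate"] <= e["low"]
    }
    if (!ok) {
      stop("config error: effects for index '", spec$index[i],
           "' are not monotone across groups in the declared direction")
    }
  }
  counts <- round(group_props * G)
  counts["low"] <- G - counts["high"] - counts["moderate"]
  if (any(counts < 1)) stop("config error: every group needs >= 1 genotype")
  structure(
    list(G = G, group_counts = counts, spec = spec,
         baseline = baseline[spec$index], baseline_cv = baseline_cv,
         effects = effects[spec$index, , drop = FALSE],
         group_centers = group_centers, jitter_sd = jitter_sd,
         noise_cv = noise_cv, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# field-plausible control baselines for the default 13-index panel
default_baseline <- function() {
  c(PH = 33, CW = 45, LL = 37, LW = 1.4, LA = 37,
    Chl = 1.08, Chl_a = 0.80, Chl_b = 0.29, Chl_ab = 2.87, Car = 0.49,
    RWC = 85, EL = 40, MDA = 30)
}

# signed treatment effects (fraction of baseline) per resistance group:
# growth and RWC shrink more in susceptible genotypes, pigments rise in
# resistant ones, damage markers (EL, MDA) rise most in susceptible ones
default_effects <- function() {
  m <- rbind(
    PH     = c(-0.02, -0.08, -0.16),
    CW     = c(-0.02, -0.08, -0.16),
    LL     = c(-0.02, -0.08, -0.16),
    LW     = c(-0.02, -0.08, -0.16),
    LA     = c(-0.04, -0.15, -0.30),
    Chl    = c( 0.35,  0.12, -0.05),
    Chl_a  = c( 0.35,  0.12, -0.05),
    Chl_b  = c( 0.45,  0.15, -0.05),
    Chl_ab = c( 0.08,  0.04,  0.00),
    Car    = c( 0.30,  0.15,  0.02),
    RWC    = c(-0.03, -0.08, -0.14),
    EL     = c( 0.10,  0.40,  0.85),
    MDA    = c( 0.15,  0.45,  0.90)
  )
  colnames(m) <- c("high", "moderate", "low")
  m
}

# piecewise-linear effect vs latent score through the three group anchor
# points, extended linearly beyond the outer anchors (monotone by the
# config validation)
interp_effect <- function(s, centers, e_high, e_mod, e_low) {
  x <- c(centers["low"], centers["moderate"], centers["high"])
  y <- c(e_low, e_mod, e_high)
  lo_slope <- (y[2] - y[1]) / (x[2] - x[1])
  hi_slope <- (y[3] - y[2]) / (x[3] - x[2])
  ifelse(s <= x[2], y[2] + (s - x[2]) * lo_slope,
                    y[2] + (s - x[2]) * hi_slope)
}

#' Generate a synthetic replicated panel with planted resistance structure
#'
#' Control replicate values are baseline x genotype-level variation x
#' multiplicative noise; treatment values additionally carry the
#' latent-score-interpolated group effect, so the treatment/control ratio
#' of a genotype is 1 + effect (exactly, in the noise-free limit). The
#' generator is fully deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `traits` (a [trait_matrix()]) and `truth`
#'   (data.frame: `genotype`, `group`, `latent` planted resistance score).
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  G <- cfg$G
  genos <- paste0("S", seq_len(G))
  groups <- sample(rep(c("high", "moderate", "low"), cfg$group_counts))
  jit <- pmin(pmax(stats::rnorm(G, 0, cfg$jitter_sd), -0.15), 0.15)
  latent <- cfg$group_centers[groups] + jit
  names(latent) <- genos

  spec <- cfg$spec
  p <- nrow(spec)
  # genotype-level control baselines (positive, clipped at 3 SD)
  z <- matrix(pmin(pmax(stats::rnorm(G * p), -3), 3), G, p)
  ctl_mean <- sweep(1 + cfg$baseline_cv * z, 2, cfg$baseline, `*`)
  dimnames(ctl_mean) <- list(genos, spec$index)

  eff <- matrix(NA_real_, G, p, dimnames = list(genos, spec$index))
  for (j in seq_len(p)) {
    e <- cfg$effects[j, ]
    eff[, j] <- interp_effect(latent, cfg$group_centers,
                              e["high"], e["moderate"], e["low"])
  }
  trt_mean <- ctl_mean * (1 + eff)

  nrep <- cfg$replicates
  noise <- function(n) 1 + cfg$noise_cv * stats::rnorm(n)
  rows <- vector("list", 2L)
  for (cond in c("control", "treatment")) {
    mu <- if (cond == "control") ctl_mean else trt_mean
    vals <- as.vector(vapply(seq_len(nrep), function(r) mu * noise(G * p),
                             matrix(0, G, p)))
    rows[[cond]] <- data.frame(
      genotype = rep(rep(genos, p), nrep),
      index = rep(rep(spec$index, each = G), nrep),
      condition = cond,
      replicate = rep(seq_len(nrep), each = G * p),
      value = vals,
      stringsAsFactors = FALSE
    )
  }
  long <- rbind(rows[["control"]], rows[["treatment"]])
  # panel display order: genotype-major
  long <- long[order(match(long$genotype, genos), match(long$index, spec$index),
                     long$condition, long$replicate), ]
  tm <- trait_matrix(long, spec = spec)
  truth <- data.frame(genotype = genos, group = groups,
                      latent = unname(latent), stringsAsFactors = FALSE)
  list(traits = tm, truth = truth)
}
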