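#' Index specification table
#'
#' An index specification declares, for every measured trait ("index"), its
#' direction of association with drought resistance and its measurement
#' units. The direction drives the fuzzy membership transform: a
#' \emph{positive} index (e.g. leaf relative water content) maps its maximum
#' to membership 1, while a \emph{negative} index (e.g. electrolyte leakage,
#' malondialdehyde) is inverted so that damage markers score low.
#'
#' @param index character vector of unique index names.
#' @param direction character vector, `"positive"` or `"negative"`, recycled
#'   if length 1.
#' @param units free-text units per index (recycled).
#' @return A `data.frame` of class `index_spec` with columns `index`,
#'   `direction`, `units`.
#' @seealso [default_index_spec()] for the bundled 13-trait panel layout.
#' @export
#' @examples
#' index_spec(c("RWC", "EL"), c("positive", "negative"), c("%", "%"))
index_spec <- function(index, direction = "positive", units = "") {
  index <- as.character(index)
  if (anyDuplicated(index)) {
    stop("index names must be unique: ",
         paste(unique(index[duplicated(index)]), collapse = ", "))
  }
  direction <- rep_len(as.character(direction), length(index))
  bad <- !direction %in% c("positive", "negative")
  if (any(bad)) {
    stop("direction must be 'positive' or 'negative' (got '",
         direction[which(bad)[1]], "')")
  }
  out <- data.frame(index = index, direction = direction,
                    units = rep_len(as.character(units), length(index)),
                    stringsAsFactors = FALSE)
  class(out) <- c("index_spec", "data.frame")
  out
}

#' Default 13-index specification for a drought phenotyping panel
#'
#' Five growth indices (plant height PH, canopy width CW, leaf length LL,
#' leaf width LW, leaf area LA), five pigment indices (total chlorophyll
#' Chl, Chl_a, Chl_b, the Chl_ab ratio, carotenoids Car), leaf relative
#' water content (RWC), electrolyte leakage (EL) and malondialdehyde (MDA).
#' EL and MDA are damage markers and therefore negatively associated with
#' resistance; all other indices are positive.
#'
#' @return An [index_spec()] with 13 rows.
#' @export
default_index_spec <- function() {
  index_spec(
    index = c("PH", "CW", "LL", "LW", "LA",
              "Chl", "Chl_a", "Chl_b", "Chl_ab", "Car",
              "RWC", "EL", "MDA"),
    direction = c(rep("positive", 11), "negative", "negative"),
    units = c("cm", "cm", "cm", "cm", "cm2",
              "mg/g FW", "mg/g FW", "mg/g FW", "ratio", "mg/g FW",
              "%", "%", "umol/g FW")
  )
}

#' Read an index specification from CSV or YAML
#'
#' CSV needs columns `index`, `direction` and optionally `units`. A YAML
#' file (requires the optional \pkg{yaml} package) is a mapping
#' `index: {direction: ..., units: ...}`.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` vs CSV).
#' @return An [index_spec()].
#' @export
read_index_spec <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML index specs requires the 'yaml' package")
    }
    lst <- yaml::read_yaml(path)
    return(index_spec(
      index = names(lst),
      direction = vapply(lst, function(x) x$direction %||% "positive", ""),
      units = vapply(lst, function(x) x$units %||% "", "")
    ))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "direction") %in% names(df))) {
    stop("index spec CSV must have columns 'index' and 'direction'")
  }
  index_spec(df$index, df$direction, if ("units" %in% names(df)) df$units else "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a genotype-by-trait panel
#'
#' The panel is stored in tidy (long) form: one row per (genotype, index,
#' condition, replicate) observation. Every (genotype, index, condition)
#' cell must hold at least one finite value and keys must be unique; cells
#' may have different replicate counts. Genotype and index display order is
#' first-appearance order and is preserved by all downstream operations.
#'
#' @param data data.frame with columns `genotype`, `index`, `condition`,
#'   `replicate`, `value`.
#' @param spec an [index_spec()] covering every index in `data`, or `NULL`
#'   to derive a positive-direction spec from the data (membership
#'   transformation then requires an explicit spec).
#' @return A `trait_matrix` object.
#' @export
trait_matrix <- function(data, spec = NULL) {
  req <- c("genotype", "index", "condition", "replicate", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  }
  data <- as.data.frame(data)[req]
  data$genotype <- as.character(data$genotype)
  data$index <- as.character(data$index)
  data$condition <- as.character(data$condition)
  rep_num <- suppressWarnings(as.integer(data$replicate))
  if (!anyNA(rep_num)) data$replicate <- rep_num
  bad_cond <- setdiff(unique(data$condition), c("control", "treatment"))
  if (length(bad_cond)) {
    stop("format error: condition must be 'control' or 'treatment', got: ",
         paste(bad_cond, collapse = ", "))
  }
  if (!is.numeric(data$value)) {
    v <- suppressWarnings(as.numeric(data$value))
    if (anyNA(v) & !anyNA(data$value)) {
      stop("parse error: non-numeric value at row ",
           which(is.na(v))[1])
    }
    data$value <- v
  }
  if (any(!is.finite(data$value))) {
    stop("parse error: non-finite value at row ",
         which(!is.finite(data$value))[1])
  }
  key <- paste(data$genotype, data$index, data$condition, data$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("integrity error: duplicated (genotype,index,condition,replicate) key: ",
         gsub("\r", "/", d))
  }
  genotypes <- unique(data$genotype)
  indices <- unique(data$index)
  if (is.null(spec)) {
    spec <- index_spec(indices)
  } else {
    extra <- setdiff(indices, spec$index)
    if (length(extra)) {
      stop("spec error: index present in data but absent from spec: ",
           paste(extra, collapse = ", "))
    }
  }
  # balance check: every genotype x index x present condition cell filled
  conds <- unique(data$condition)
  cell <- unique(data[c("genotype", "index", "condition")])
  expected <- length(genotypes) * length(indices) * length(conds)
  if (nrow(cell) != expected) {
    full <- expand.grid(genotype = genotypes, index = indices,
                        condition = conds, stringsAsFactors = FALSE)
    have <- paste(cell$genotype, cell$index, cell$condition)
    want <- paste(full$genotype, full$index, full$condition)
    miss <- full[!want %in% have, , drop = FALSE][1, ]
    stop("integrity error: missing cell (",
         miss$genotype, ", ", miss$index, ", ", miss$condition, ")")
  }
  structure(
    list(data = data, genotypes = genotypes, indices = indices,
         conditions = conds, spec = spec),
    class = "trait_matrix"
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Genotype-by-trait panel:",
      length(x$genotypes), "genotypes x", length(x$indices), "indices,",
      "conditions:", paste(x$conditions, collapse = "/"),
      sprintf("(%d observations)\n", nrow(x$data)))
  invisible(x)
}

#' Read a tidy genotype-by-trait CSV
#'
#' Expects header columns `genotype,index,condition,replicate,value`
#' (UTF-8). Row order in the file does not affect the resulting panel
#' beyond first-appearance display order of genotypes and indices.
#'
#' @param path CSV file path.
#' @param spec optional [index_spec()]; every index in the file must be
#'   declared in it.
#' @return A [trait_matrix()].
#' @export
read_trait_table <- function(path, spec = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("genotype", "index", "condition", "replicate", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("format error: '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v)) {
    stop("parse error: non-numeric value at data row ", which(is.na(v))[1],
         " of ", path)
  }
  df$value <- v
  trait_matrix(df, spec = spec)
}

#' Write a panel back to tidy CSV
#'
#' Values are written with [as.character()] so that decimal strings read by
#' [read_trait_table()] round-trip unchanged.
#'
#' @param tm a [trait_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(tm, path) {
  stopifnot(inherits(tm, "trait_matrix"))
  df <- tm$data
  df$value <- as.character(df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide matrix of cell means
#'
#' Convenience reader for a `genotype` column plus one column per
#' `<index>_<condition>` combination (e.g. `RWC_control`). The result is
#' normalized to a tidy single-replicate [trait_matrix()].
#'
#' @param path CSV path.
#' @param spec optional [index_spec()].
#' @return A [trait_matrix()] with one replicate per cell.
#' @export
read_wide_means <- function(path, spec = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"genotype" %in% names(df)) {
    stop("format error: wide means CSV needs a 'genotype' column")
  }
  cols <- setdiff(names(df), "genotype")
  m <- regmatches(cols, regexec("^(.*)_(control|treatment)$", cols))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop("format error: column '", cols[bad][1],
         "' is not of the form <index>_<condition>")
  }
  long <- do.call(rbind, lapply(seq_along(cols), function(i) {
    data.frame(genotype = df$genotype,
               index = m[[i]][2], condition = m[[i]][3],
               replicate = 1L, value = df[[cols[i]]],
               stringsAsFactors = FALSE)
  }))
  trait_matrix(long, spec = spec)
}

#' Per-cell means and standard deviations
#'
#' Aggregates replicates to the (genotype, index, condition) level.
#' Standard deviation uses the sample (n-1) convention and is 0 for
#' single-replicate cells, so aggregation of an already-aggregated panel is
#' idempotent.
#'
#' @param tm a [trait_matrix()].
#' @return data.frame with columns `genotype`, `index`, `condition`,
#'   `mean`, `sd`, `n`, ordered by the panel's display order.
#' @export
cell_means <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  d <- tm$data
  f <- list(genotype = factor(d$genotype, levels = tm$genotypes),
            index = factor(d$index, levels = tm$indices),
            condition = factor(d$condition, levels = tm$conditions))
  agg <- aggregate(d$value, f, function(v) {
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      n = length(v))
  })
  out <- data.frame(genotype = as.character(agg$genotype),
                    index = as.character(agg$index),
                    condition = as.character(agg$condition),
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = as.integer(agg$x[, "n"]),
                    stringsAsFactors = FALSE)
  ord <- order(match(out$genotype, tm$genotypes),
               match(out$index, tm$indices),
               match(out$condition, tm$conditions))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype-by-index matrix of cell means for one condition
#'
#' @param tm a [trait_matrix()].
#' @param condition `"control"` or `"treatment"`.
#' @return numeric matrix, genotypes in rows (panel order), indices in
#'   columns.
#' @export
means_matrix <- function(tm, condition = c("treatment", "control")) {
  condition <- match.arg(condition)
  cm <- cell_means(tm)
  cm <- cm[cm$condition == condition, , drop = FALSE]
  out <- matrix(NA_real_, length(tm$genotypes), length(tm$indices),
                dimnames = list(tm$genotypes, tm$indices))
  out[cbind(cm$genotype, cm$index)] <- cm$mean
  out
}
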