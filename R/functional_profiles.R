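# Count tables are plain integer matrices: rows = features (KO ids or CAZyme
# family names), columns = samples. Grouping vectors (age classes) are passed
# separately, aligned with the columns.

check_count_table <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    stop("count table must be a matrix with feature rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  invisible(counts)
}

#' Relative abundance of features within each sample
#'
#' Divides each feature's count by the total number of reads matching the
#' database in that sample, so that columns sum to 1.
#'
#' @param counts count table (features x samples matrix).
#' @return matrix of proportions, same shape as `counts`.
#' @export
relative_abundance <- function(counts) {
  check_count_table(counts)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts, 2, tot, "/")
}

#' Single-copy marker-gene normalization
#'
#' Divides every feature's count by the count of a universally single-copy
#' marker gene in the same sample, approximating per-genome copy number. The
#' default marker is the large-subunit ribosomal protein L14 (K02874);
#' ribosomal proteins S6 (K02990 family: K02950, K02992) and initiation
#' factor-class markers such as K02519 are conventional alternatives, and
#' results should be robust to the choice.
#'
#' @param counts count table (features x samples matrix).
#' @param marker_id feature id of the marker gene (default `"K02874"`).
#' @return matrix of per-marker ratios (the marker row is identically 1).
#' @export
marker_normalize <- function(counts, marker_id = "K02874") {
  check_count_table(counts)
  if (!marker_id %in% rownames(counts)) {
    stop("marker gene ", marker_id, " absent from count table")
  }
  mk <- counts[marker_id, ]
  if (any(mk == 0)) {
    stop("marker gene ", marker_id, " has zero counts in sample(s): ",
         paste(colnames(counts)[mk == 0], collapse = ", "))
  }
  sweep(counts, 2, mk, "/")
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p * ln p)` over a proportion vector, with the convention
#' `0 * ln 0 = 0`. With S nonzero features, `0 <= H <= ln S`, the maximum
#' attained on the uniform distribution. The natural-log base matches
#' conventional reporting for functional-gene diversity; pass `base` to
#' change it.
#'
#' @param p proportion vector summing to 1 (zeros allowed), or a matrix of
#'   proportions with samples in columns (e.g. from
#'   [relative_abundance()]), in which case one H per column is returned.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return numeric: H, or a named vector of H per sample.
#' @export
shannon_diversity <- function(p, base = exp(1)) {
  if (is.matrix(p)) {
    return(apply(p, 2, shannon_diversity, base = base))
  }
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Screen features for age-class effects
#'
#' Runs a one-way ANOVA of relative abundance on the grouping factor for
#' every feature and flags those with raw `p < alpha` as affected. By
#' default no multiple-testing correction is applied (each family is judged
#' against the raw threshold); set `adjust = "BH"` for
#' Benjamini-Hochberg-adjusted decisions.
#'
#' The F statistics are computed by a vectorized matrix decomposition of the
#' between/within sums of squares (equivalent to `aov()` per feature, but
#' scaling to thousands of features). Features with zero variance everywhere
#' and equal group means cannot show differences and get `p = 1`.
#'
#' @param counts count table (features x samples). Converted to relative
#'   abundances internally unless `is_relative = TRUE`.
#' @param groups factor of age-class labels, one per sample column; at least
#'   two groups with at least two replicates each.
#' @param alpha significance threshold on the (possibly adjusted) p-value
#'   (default 0.01).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @param is_relative set `TRUE` if `counts` already holds proportions.
#' @return data frame with columns `feature`, `p`, `p_adjusted`, `affected`.
#' @export
per_family_screen <- function(counts, groups, alpha = 0.01,
                              adjust = "none", is_relative = FALSE) {
  check_count_table(counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts))
  if (nlevels(droplevels(groups)) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("need at least two replicates per group")
  x <- if (is_relative) counts else relative_abundance(counts)
  n <- ncol(x)
  k <- nlevels(groups)
  g <- stats::model.matrix(~ groups - 1)            # samples x groups
  ng <- colSums(g)
  gm <- x %*% g %*% diag(1 / ng, k)                 # feature x group means
  grand <- rowMeans(x)                              # feature grand means
  ss_between <- rowSums(sweep(gm, 1, grand)^2 %*% diag(ng, k))
  fitted <- gm %*% t(g)                             # per-sample group mean
  ss_within <- rowSums((x - fitted)^2)
  df1 <- k - 1L
  df2 <- n - k
  f_stat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  # degenerate rule: no within-group variance and no between-group signal
  degen <- ss_within < 1e-300 & ss_between < 1e-300
  p[degen] <- 1
  # zero within-variance but real separation: p -> 0
  sep <- ss_within < 1e-300 & ss_between >= 1e-300
  p[sep] <- 0
  p_adj <- stats::p.adjust(p, method = adjust)
  data.frame(feature = rownames(x), p = p, p_adjusted = p_adj,
             affected = p_adj < alpha, row.names = NULL)
}

#' Read / write count tables as TSV
#'
#' Feature-by-sample tab-separated tables with feature ids in the first
#' column.
#'
#' @param path file path.
#' @return `read_count_table()` returns an integer matrix.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  check_count_table(m)
}

#' @rdname read_count_table
#' @param counts count table matrix.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
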