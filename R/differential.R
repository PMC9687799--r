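#' Differential-expression thresholds
#'
#' Defaults follow the stringent filter used for the headline burden-band
#' comparisons: |log2 fold change| > 1.25, p < 0.0005, BH FDR < 0.05. For
#' matrices that have been min-max transformed per gene (values on
#' `[0, 1]`), the fold-change threshold drops to 0.25 since a full unit is
#' the gene's whole dynamic range.
#'
#' @param fc Fold-change threshold on the log2 (or shifted) scale.
#' @param p Raw p-value threshold.
#' @param fdr Benjamini-Hochberg FDR threshold.
#' @param test `"welch"` (Welch t-test, default) or `"wilcoxon"`
#'   (Mann-Whitney U).
#' @return A list of thresholds.
#' @export
de_config <- function(fc = 1.25, p = 0.0005, fdr = 0.05,
                      test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(fc >= 0, p > 0, p <= 1, fdr > 0, fdr <= 1)
  list(fc = fc, p = p, fdr = fdr, test = test)
}

de_empty <- function() {
  data.frame(gene_id = character(), comparison = character(),
             log2fc = numeric(), p_value = numeric(), fdr = numeric(),
             significant = logical(), stringsAsFactors = FALSE)
}

flag_significant <- function(df, config) {
  df$significant <- abs(df$log2fc) > config$fc &
    df$p_value < config$p & df$fdr < config$fdr
  df
}

# vectorised Welch t-test over the rows of two matrices
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  # both groups constant: exact equality -> no evidence (p = 1); different
  # means with zero variance -> limiting p = 0
  flat <- se2 == 0
  p[flat] <- ifelse(ma[flat] == mb[flat], 1, 0)
  p
}

#' Differential expression between two TcB bands
#'
#' Per gene, the effect is the difference of group means on the log2 scale
#' (`mean(group B) - mean(group A)` for `pair = c(A, B)`), the p-value comes
#' from a Welch t-test (or Mann-Whitney U), and BH adjustment runs across all
#' tested genes. A gene is flagged significant when it passes the fold-change,
#' p and FDR filters jointly.
#'
#' @param matrix A log2-scale `tcb_matrix`.
#' @param groups Output of [assign_tcb_groups()].
#' @param pair Ordered character pair `c(reference, treatment)`; the
#'   comparison label is `"<treatment>_vs_<reference>"`.
#' @param config A [de_config()].
#' @param min_group Minimum samples per band (default 3); smaller bands are
#'   skipped with a warning and an empty table is returned.
#' @return Data frame of `gene_id`, `comparison`, `log2fc`, `p_value`, `fdr`,
#'   `significant`.
#' @export
between_group_de <- function(matrix, groups, pair = c("low", "high"),
                             config = de_config(), min_group = 3L) {
  assert_log2(matrix, "between_group_de")
  stopifnot(length(pair) == 2L)
  ids_a <- group_samples(groups, pair[1L], min_group)
  ids_b <- group_samples(groups, pair[2L], min_group)
  if (is.null(ids_a) || is.null(ids_b)) return(de_empty())
  v <- em_values(matrix)
  a <- v[, ids_a, drop = FALSE]
  b <- v[, ids_b, drop = FALSE]
  log2fc <- rowMeans(b) - rowMeans(a)
  p <- if (config$test == "welch") {
    welch_rows(a, b)
  } else {
    vapply(seq_len(nrow(v)), function(i) {
      if (all(a[i, ] == b[i, 1L]) && all(b[i, ] == b[i, 1L])) return(1)
      suppressWarnings(stats::wilcox.test(a[i, ], b[i, ])$p.value)
    }, numeric(1L))
  }
  out <- data.frame(gene_id = rownames(v),
                    comparison = paste0(pair[2L], "_vs_", pair[1L]),
                    log2fc = unname(log2fc),
                    p_value = unname(p),
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  flag_significant(out, config)
}

#' Within-group deviation from the group median
#'
#' For a single band, each gene is referenced against its own median within
#' the band; the per-sample deviations (value minus reference) are summarised
#' by their mean and tested against zero with a one-sample Wilcoxon
#' signed-rank test, BH-adjusted across genes.
#'
#' @param matrix A log2-scale `tcb_matrix`.
#' @param groups Output of [assign_tcb_groups()].
#' @param group Band name, e.g. `"high"`.
#' @param config A [de_config()].
#' @param min_group Minimum band size (default 3).
#' @return Data frame in the same shape as [between_group_de()]; `log2fc`
#'   holds the mean deviation from the group median.
#' @export
within_group_deviation <- function(matrix, groups, group = "high",
                                   config = de_config(), min_group = 3L) {
  assert_log2(matrix, "within_group_deviation")
  ids <- group_samples(groups, group, min_group)
  if (is.null(ids)) return(de_empty())
  v <- em_values(matrix)[, ids, drop = FALSE]
  ref <- apply(v, 1L, stats::median)
  dev <- v - ref
  mean_dev <- rowMeans(dev)
  p <- vapply(seq_len(nrow(dev)), function(i) {
    d <- dev[i, ]
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(d, mu = 0)$p.value)
  }, numeric(1L))
  out <- data.frame(gene_id = rownames(v),
                    comparison = paste0(group, "_vs_group_median"),
                    log2fc = unname(mean_dev),
                    p_value = unname(p),
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  flag_significant(out, config)
}

#' Import a differential-expression table computed externally
#'
#' Count-model tools (edgeR, DESeq2) are not re-implemented here; their
#' output can be imported and run through the same significance flagging as
#' the built-in tests. Required columns: `gene_id`, `log2fc`, `p_value`;
#' `fdr` is recomputed by BH when absent.
#'
#' @param path TSV path.
#' @param config A [de_config()].
#' @param comparison Label to attach when the file has no `comparison` column.
#' @return Data frame in the shape of [between_group_de()].
#' @export
import_external_de <- function(path, config = de_config(),
                               comparison = "external") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("gene_id", "log2fc", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("external DE table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$p_value)) || any(df$p_value < 0) || any(df$p_value > 1)) {
    stop("external DE table has p_value outside [0, 1]", call. = FALSE)
  }
  if (is.null(df$fdr)) {
    df$fdr <- stats::p.adjust(df$p_value, method = "BH")
  } else if (any(!is.finite(df$fdr)) || any(df$fdr < 0) || any(df$fdr > 1)) {
    stop("external DE table has fdr outside [0, 1]", call. = FALSE)
  }
  if (is.null(df$comparison)) df$comparison <- comparison
  out <- df[, c("gene_id", "comparison", "log2fc", "p_value", "fdr")]
  flag_significant(out, config)
}
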