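#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test of the overlap between a significant-gene
#' list and each gene set, within a stated universe. The universe should be
#' the genes actually analysed (the matrix rows), not the union of the GMT:
#' this matches the universe of the differential test that produced the
#' list. Sets are intersected with the universe before testing; sets with
#' zero overlap are still reported. BH adjustment runs across all tested
#' sets, and a set is significant when it passes both the raw-p and FDR
#' filters.
#'
#' @param gene_list Character vector of hit genes; must be a subset of
#'   `universe`.
#' @param universe Character vector of all tested genes.
#' @param sets A [gene_set_collection()].
#' @param p_max Raw p threshold (default 1e-4).
#' @param fdr_max BH FDR threshold (default 0.05).
#' @param blacklist Character vector of set names to drop before testing;
#'   ambiguous catch-all categories (e.g. "disease", "development") can be
#'   excluded this way. Matched case-insensitively against set names.
#' @return Data frame with `set_name`, `overlap`, `set_size`, `list_size`,
#'   `universe_size`, `p_value`, `fdr`, `significant`.
#' @export
hypergeometric_enrichment <- function(gene_list, universe, sets,
                                      p_max = 1e-4, fdr_max = 0.05,
                                      blacklist = character()) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    stop("gene_list contains genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- !(tolower(names(sets$sets)) %in% tolower(blacklist))
  set_list <- sets$sets[keep]
  n_u <- length(universe)
  n_l <- length(gene_list)
  rows <- lapply(names(set_list), function(nm) {
    s <- intersect(set_list[[nm]], universe)
    k <- length(intersect(s, gene_list))
    p <- if (n_l == 0L || length(s) == 0L) {
      1
    } else {
      stats::phyper(k - 1L, length(s), n_u - length(s), n_l,
                    lower.tail = FALSE)
    }
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               list_size = n_l, universe_size = n_u, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), list_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_max & out$fdr < fdr_max
  out
}

#' Collapse pathways into higher-order process summaries
#'
#' Aggregates gene sets into curated higher-order categories (translation,
#' TCA/electron transport, transcription, cell cycle, extracellular
#' matrix, ...): per category, the member genes are the union over its
#' pathways, each sample is summarised by the mean log2 expression of those
#' genes, and each TcB band by the median of its samples' means. Genes
#' absent from the matrix are ignored and reported in a coverage table;
#' categories with no matched gene are dropped with a warning.
#'
#' @param matrix A log2-scale `tcb_matrix`.
#' @param sets A [gene_set_collection()] with a non-empty `category_map`.
#' @param groups Optional output of [assign_tcb_groups()]; when given, the
#'   per-band medians are computed for the low/mid/high bands.
#' @return List of class `"higher_order_summary"` with elements
#'   `sample_means` (categories x samples matrix), `group_medians`
#'   (categories x bands matrix, or `NULL`), and `coverage` (data frame of
#'   matched/total member genes per category).
#' @export
collapse_to_higher_order <- function(matrix, sets, groups = NULL) {
  assert_log2(matrix, "collapse_to_higher_order")
  cmap <- sets$category_map
  if (is.null(cmap) || !length(cmap)) {
    stop("gene-set collection has no category map", call. = FALSE)
  }
  v <- em_values(matrix)
  cats <- unique(unname(cmap))
  sample_means <- matrix(NA_real_, nrow = 0L, ncol = ncol(v),
                         dimnames = list(NULL, colnames(v)))
  coverage <- list()
  for (cat in cats) {
    members <- unique(unlist(sets$sets[names(cmap)[cmap == cat]],
                             use.names = FALSE))
    hit <- intersect(members, rownames(v))
    coverage[[cat]] <- data.frame(category = cat, matched = length(hit),
                                  total = length(members),
                                  stringsAsFactors = FALSE)
    if (!length(hit)) {
      warning(sprintf("category '%s' has no gene in the matrix; dropped", cat),
              call. = FALSE)
      next
    }
    sample_means <- rbind(sample_means,
                          matrix(colMeans(v[hit, , drop = FALSE]), nrow = 1L,
                                 dimnames = list(cat, colnames(v))))
  }
  group_medians <- NULL
  if (!is.null(groups) && nrow(sample_means)) {
    bands <- intersect(c("low", "mid", "high"), unique(as.character(groups$group)))
    group_medians <- sapply(bands, function(b) {
      ids <- intersect(groups$sample_id[groups$group == b], colnames(sample_means))
      apply(sample_means[, ids, drop = FALSE], 1L, stats::median)
    })
    if (is.null(dim(group_medians))) {
      group_medians <- matrix(group_medians, ncol = length(bands),
                              dimnames = list(rownames(sample_means), bands))
    }
  }
  structure(list(sample_means = sample_means,
                 group_medians = group_medians,
                 coverage = do.call(rbind, unname(coverage))),
            class = "higher_order_summary")
}

#' @export
print.higher_order_summary <- function(x, ...) {
  cat(sprintf("<higher_order_summary> %d categories x %d samples\n",
              nrow(x$sample_means), ncol(x$sample_means)))
  if (!is.null(x$group_medians)) print(round(x$group_medians, 3))
  invisible(x)
}
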