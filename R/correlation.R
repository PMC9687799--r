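#' Spearman screen of genes against the TcB axis
#'
#' Correlates every gene's expression vector with the samples' TcB values by
#' Spearman rank correlation (average ranks for ties). Two-sided p-values use
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`; for n <= 9 samples
#' the exact null distribution is used instead (via [stats::cor.test()];
#' with ties the approximation is used throughout). Constant genes have no
#' defined rank correlation and are emitted with `rho = 0`, `p = 1` and a
#' `degenerate` flag rather than dropped.
#'
#' @param matrix A log2-scale `tcb_matrix`.
#' @param tcb Data frame from [compute_tcb()] covering every sample.
#' @return Data frame with `gene_id`, `rho`, `p_value`, `degenerate`.
#' @export
tcb_gene_correlation <- function(matrix, tcb) {
  assert_log2(matrix, "tcb_gene_correlation")
  miss <- setdiff(colnames(matrix), tcb$sample_id)
  if (length(miss)) stop("no TcB value for sample(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  y <- tcb$tcb[match(colnames(matrix), tcb$sample_id)]
  n <- length(y)
  if (n < 4L) stop("correlation screen needs >= 4 samples", call. = FALSE)
  v <- em_values(matrix)
  constant <- apply(v, 1L, function(x) max(x) == min(x))
  ry <- rank(y)
  rx <- t(apply(v, 1L, rank))
  rho <- suppressWarnings(as.vector(stats::cor(t(rx), ry)))
  rho[constant] <- 0
  exact_ok <- n <= 9L && !anyDuplicated(y)
  p <- if (exact_ok) {
    vapply(seq_len(nrow(v)), function(i) {
      if (constant[i]) return(1)
      suppressWarnings(stats::cor.test(v[i, ], y, method = "spearman",
                                       exact = TRUE)$p.value)
    }, numeric(1L))
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    pv <- 2 * stats::pt(-abs(tt), n - 2)
    pv[abs(rho) >= 1] <- 0
    pv
  }
  p[constant] <- 1
  p <- pmin(p, 1)
  data.frame(gene_id = rownames(v), rho = unname(rho), p_value = unname(p),
             degenerate = unname(constant), stringsAsFactors = FALSE)
}

#' Select the top burden-correlated genes
#'
#' Applies the screening filter: positively selected genes need
#' `rho > r_pos` and `p < p_max`, negatively selected genes `rho < r_neg` and
#' `p < p_max`; each list is ranked by correlation strength and truncated to
#' `top_n`. The raw p filter is deliberate -- no multiplicity adjustment is
#' applied at this screening stage. Rank ties beyond the cap are broken
#' lexicographically by gene ID for determinism.
#'
#' @param records Output of [tcb_gene_correlation()].
#' @param r_pos,r_neg Correlation bounds (defaults 0.75 and -0.75).
#' @param p_max Raw p-value bound (default 1e-4).
#' @param top_n Cap per list (default 50); lists may come up shorter.
#' @return List with elements `positive` and `negative` (ranked data frames)
#'   and `records` (the input annotated with a `selected` column taking
#'   values `positive_top`, `negative_top`, `none`).
#' @export
select_top_correlated <- function(records, r_pos = 0.75, r_neg = -0.75,
                                  p_max = 1e-4, top_n = 50L) {
  stopifnot(r_pos > r_neg, p_max > 0, top_n >= 0)
  pos <- records[records$rho > r_pos & records$p_value < p_max &
                   !records$degenerate, , drop = FALSE]
  pos <- pos[order(-pos$rho, pos$gene_id, method = "radix"), , drop = FALSE]
  pos <- utils::head(pos, top_n)
  neg <- records[records$rho < r_neg & records$p_value < p_max &
                   !records$degenerate, , drop = FALSE]
  neg <- neg[order(neg$rho, neg$gene_id, method = "radix"), , drop = FALSE]
  neg <- utils::head(neg, top_n)
  records$selected <- "none"
  records$selected[records$gene_id %in% pos$gene_id] <- "positive_top"
  records$selected[records$gene_id %in% neg$gene_id] <- "negative_top"
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg, records = records)
}
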