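#' Min-max ("median shift") scaling onto [0, 1]
#'
#' The core transform of the burden pipeline:
#' `shift = (value - range minimum) / range`. The minimum maps to 0, the
#' maximum to 1, and the map is order-preserving and invariant to positive
#' affine changes of the input. Despite the field name "median shift", no
#' median enters the formula.
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @param degenerate What to do when all values are equal (range 0):
#'   `"error"` (default) or `"zeros"` (map everything to 0, useful for
#'   pathological fixtures).
#' @return Numeric vector in `[0, 1]`, same length and names as `values`.
#' @examples
#' median_shift(c(2, 4, 6)) # 0 0.5 1
#' @export
median_shift <- function(values, degenerate = c("error", "zeros")) {
  degenerate <- match.arg(degenerate)
  if (length(values) < 2L) stop("median_shift needs at least 2 values",
                                call. = FALSE)
  if (any(!is.finite(values))) stop("median_shift: non-finite input",
                                    call. = FALSE)
  rng <- range(values)
  span <- rng[2L] - rng[1L]
  if (span == 0) {
    if (degenerate == "error") {
      stop("median_shift: degenerate range (all values equal)", call. = FALSE)
    }
    return(stats::setNames(rep(0, length(values)), names(values)))
  }
  (values - rng[1L]) / span
}

#' Log2-transform a raw-scale expression matrix
#'
#' @param matrix A raw-scale `tcb_matrix`.
#' @param pseudocount Non-negative value added before taking log2 (default 1,
#'   so zero counts map to 0).
#' @return A log2-scale `tcb_matrix`. If the input is already log2, it is
#'   returned unchanged with a warning (never double-logged).
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  if (expr_scale(matrix) == "log2") {
    warning("matrix is already log2-scale; returning it unchanged")
    return(matrix)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("`pseudocount` must be a single non-negative number", call. = FALSE)
  }
  v <- em_values(matrix) + pseudocount
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("log2 undefined: value + pseudocount <= 0 at gene '%s', sample '%s'",
                 rownames(matrix)[bad[1L]], colnames(matrix)[bad[2L]]),
         call. = FALSE)
  }
  expression_matrix(log2(v), scale = "log2")
}

#' Transcriptomic burden (TcB) per sample
#'
#' Sums the log2 expression values of each sample over all genes, then
#' min-max scales the sums across samples. The resulting score in `[0, 1]`
#' is a proxy for global transcriptional activity and is used as the
#' progression axis of the whole pipeline.
#'
#' @param matrix A log2-scale `tcb_matrix`.
#' @param degenerate Passed to [median_shift()].
#' @return Data frame with columns `sample_id`, `raw_sum`, `tcb`, one row per
#'   sample in matrix column order.
#' @export
compute_tcb <- function(matrix, degenerate = c("error", "zeros")) {
  assert_log2(matrix, "compute_tcb")
  sums <- colSums(em_values(matrix))
  data.frame(sample_id = colnames(matrix),
             raw_sum = unname(sums),
             tcb = unname(median_shift(sums, degenerate = degenerate)),
             stringsAsFactors = FALSE)
}

#' Gene shift: the per-gene analogue of TcB
#'
#' Two variants are provided because the per-gene statistic admits two
#' readings:
#' * `mode = "median"` (default): summarise each gene by its median log2
#'   expression across samples, then min-max scale these summaries jointly
#'   across genes. Returns one shift per gene -- the second axis of the
#'   abacus layout.
#' * `mode = "per_value"`: min-max scale each gene's own expression vector
#'   across samples, returning a genes x samples matrix in `[0, 1]`. This is
#'   the form summarised by kernel densities in longitudinal analyses.
#'
#' @param matrix A log2-scale `tcb_matrix`.
#' @param mode `"median"` or `"per_value"`.
#' @param degenerate Passed to [median_shift()] (for `per_value`, applied per
#'   gene row).
#' @return For `"median"`, a data frame with `gene_id` and `shift`; for
#'   `"per_value"`, a numeric genes x samples matrix in `[0, 1]`.
#' @export
compute_gene_shift <- function(matrix, mode = c("median", "per_value"),
                               degenerate = c("error", "zeros")) {
  mode <- match.arg(mode)
  assert_log2(matrix, "compute_gene_shift")
  v <- em_values(matrix)
  if (mode == "median") {
    med <- apply(v, 1L, stats::median)
    return(data.frame(gene_id = rownames(matrix),
                      shift = unname(median_shift(med, degenerate = degenerate)),
                      stringsAsFactors = FALSE))
  }
  degenerate <- match.arg(degenerate)
  out <- t(apply(v, 1L, median_shift, degenerate = degenerate))
  dimnames(out) <- dimnames(v)
  out
}

#' Abacus ordering of an expression matrix
#'
#' Rearranges the matrix so that samples (columns) run in increasing TcB and
#' genes (rows) in increasing gene shift, linearising the dataset along the
#' burden axis. Ties are broken lexicographically by identifier so that the
#' output is bit-reproducible. The operation is a pure permutation and is
#' idempotent.
#'
#' @param matrix A `tcb_matrix`.
#' @param tcb Output of [compute_tcb()], covering every sample of `matrix`.
#' @param gene_shift Output of [compute_gene_shift()] in `"median"` mode,
#'   covering every gene of `matrix`.
#' @return The reordered `tcb_matrix`.
#' @export
abacus_order <- function(matrix, tcb, gene_shift) {
  miss_s <- setdiff(colnames(matrix), tcb$sample_id)
  if (length(miss_s)) stop("no TcB profile for sample(s): ",
                           paste(miss_s, collapse = ", "), call. = FALSE)
  miss_g <- setdiff(rownames(matrix), gene_shift$gene_id)
  if (length(miss_g)) stop("no gene-shift profile for gene(s): ",
                           paste(miss_g, collapse = ", "), call. = FALSE)
  tcb <- tcb[match(colnames(matrix), tcb$sample_id), , drop = FALSE]
  gs <- gene_shift[match(rownames(matrix), gene_shift$gene_id), , drop = FALSE]
  col_ord <- order(tcb$tcb, tcb$sample_id, method = "radix")
  row_ord <- order(gs$shift, gs$gene_id, method = "radix")
  matrix[row_ord, col_ord]
}
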