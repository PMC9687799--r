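#' Construct an expression matrix
#'
#' The central data container of the package: a numeric genes x samples
#' matrix carrying an explicit `scale` flag. The flag is mandatory because the
#' most likely user error with harmonised public matrices is silently
#' log-transforming data that is already on the log2 scale.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty `rownames` (gene IDs) and `colnames` (sample IDs).
#' @param scale Either `"raw"` (normalized counts such as TPM/RPKM/FPKM/RSEM)
#'   or `"log2"` (already log2-transformed).
#' @return A numeric matrix of class `"tcb_matrix"` with a `scale` attribute.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("G", 1:3), c("S1", "S2")))
#' em <- expression_matrix(m, scale = "raw")
#' expr_scale(em)
#' @export
expression_matrix <- function(values, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("expression matrix needs at least 2 genes and 2 samples", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid))) {
    stop("expression matrix must have non-empty gene and sample identifiers",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gid[bad[1L]], sid[bad[2L]]), call. = FALSE)
  }
  if (scale == "raw" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("raw-scale matrix has negative value at gene '%s', sample '%s'",
                 gid[bad[1L]], sid[bad[2L]]), call. = FALSE)
  }
  structure(values, scale = scale, class = c("tcb_matrix", "matrix", "array"))
}

#' Scale flag of an expression matrix
#' @param x A `tcb_matrix`.
#' @return `"raw"` or `"log2"`.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) stop("not an expression matrix: missing scale attribute",
                        call. = FALSE)
  sc
}

#' @export
print.tcb_matrix <- function(x, ...) {
  cat(sprintf("<tcb_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  v <- unclass(x)
  attr(v, "scale") <- NULL
  print(utils::head(v[, seq_len(min(ncol(v), 6L)), drop = FALSE]), ...)
  invisible(x)
}

#' @export
`[.tcb_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sc <- attr(x, "scale")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "scale") <- sc
    class(out) <- c("tcb_matrix", "matrix", "array")
  }
  out
}

# internal: strip class for plain-matrix arithmetic
em_values <- function(x) {
  v <- unclass(x)
  attr(v, "scale") <- NULL
  v
}

assert_log2 <- function(x, what) {
  if (expr_scale(x) != "log2") {
    stop(what, " requires a log2-scale matrix; call log2_transform() first",
         call. = FALSE)
  }
  invisible(TRUE)
}
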