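#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV table with one header row and one identifier column into an
#' [expression_matrix()]. The table may have genes in rows (the usual layout:
#' header = sample IDs) or samples in rows; the returned matrix is always
#' genes x samples. Missing and non-numeric cells are rejected outright:
#' imputation, if needed, must happen upstream.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param scale Scale of the stored values, `"log2"` or `"raw"`; mandatory,
#'   there is no sniffing.
#' @param sep Field separator; default `NULL` auto-detects from the file
#'   extension (`.csv` -> comma, anything else -> tab).
#' @return A `tcb_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows"),
                                   scale = c("log2", "raw"),
                                   sep = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an ID column plus >= 1 data column",
                          call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cols <- names(df)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(cols),
                 dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    x <- df[[j + 1L]]
    missing_cell <- is.na(x) | !nzchar(trimws(x))
    num <- suppressWarnings(as.numeric(x))
    bad <- which(missing_cell | is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                   ids[bad[1L]], cols[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  expression_matrix(vals, scale = scale)
}

detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene IDs; names are set
#'   names, no set may be empty, names must be unique.
#' @param category_map Optional named character vector mapping set names to
#'   higher-order category labels (e.g. translation, TCA/ETC, cell cycle).
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, category_map = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "), call. = FALSE)
  }
  if (!is.null(category_map)) {
    if (is.null(names(category_map))) {
      stop("`category_map` must be named by set name", call. = FALSE)
    }
    category_map <- vapply(category_map, as.character, character(1L))
  }
  structure(list(sets = sets, category_map = category_map),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (%d genes total)%s\n",
              length(x$sets), length(unique(unlist(x$sets))),
              if (is.null(x$category_map)) "" else
                sprintf(", %d categorized", length(x$category_map))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Broad-dialect GMT: one set per line, tab-delimited fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description is
#' discarded; duplicate genes within a set are de-duplicated.
#'
#' @param path Path to a `.gmt` file.
#' @param category_map Optional named character vector (or path to a
#'   two-column TSV `set_name<TAB>category`) attaching higher-order categories.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, category_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    nm <- f[1L]
    if (nm %in% names(sets)) {
      stop(sprintf("GMT line %d: duplicate set name '%s'", i, nm), call. = FALSE)
    }
    sets[[nm]] <- unique(f[-(1:2)])
  }
  if (is.character(category_map) && length(category_map) == 1L &&
      is.null(names(category_map)) && file.exists(category_map)) {
    category_map <- read_category_map(category_map)
  }
  gene_set_collection(sets, category_map = category_map)
}

#' Read a pathway-to-category mapping table
#'
#' Two-column TSV (`set_name`, `category`) assigning each gene set to a
#' higher-order biological process used by [collapse_to_higher_order()].
#'
#' @param path Path to the TSV.
#' @return Named character vector (names = set names).
#' @export
read_category_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("set_name", "category")
  if (!all(need %in% names(df))) {
    stop("category map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(as.character(df$category), df$set_name)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `subject_id`, `timepoint` and optionally
#' `diagnosis`. Timepoint labels are ordered: either pass the ordered level
#' set explicitly or the order of first appearance in the file is used.
#'
#' @param path Path to the TSV.
#' @param timepoints Optional character vector giving the ordered timepoint
#'   levels; labels in the file outside this set are an error.
#' @return A data frame with `timepoint` as an ordered factor.
#' @export
read_sample_table <- function(path, timepoints = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("sample_id", "subject_id", "timepoint")
  if (!all(need %in% names(df))) {
    stop("sample table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  sample_table(df, timepoints = timepoints)
}

#' Validate an in-memory sample table
#' @param df Data frame with `sample_id`, `subject_id`, `timepoint`.
#' @inheritParams read_sample_table
#' @return The validated data frame, `timepoint` an ordered factor.
#' @export
sample_table <- function(df, timepoints = NULL) {
  timepoints <- timepoints %||% unique(as.character(df$timepoint))
  bad <- setdiff(unique(as.character(df$timepoint)), timepoints)
  if (length(bad)) {
    stop("timepoint labels outside the declared ordered set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$timepoint <- factor(as.character(df$timepoint), levels = timepoints,
                         ordered = TRUE)
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write a result table as TSV
#'
#' All pipeline outputs are plain TSV with a header row; numbers are written
#' at full double precision (>= 6 significant digits), so write/read
#' round-trips are value-preserving to well below 1e-6 relative error.
#'
#' @param records A data frame (possibly zero rows: the header is still
#'   written).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, first column `gene_id`, remaining columns the samples.
#'
#' @param matrix A `tcb_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), em_values(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
}
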