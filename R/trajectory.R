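band_rank <- function(g) {
  match(as.character(g), c("low", "mid", "high"))
}

#' Classify paired-sample TcB shifts
#'
#' For a two-timepoint design (e.g. initial diagnosis and relapse), each
#' subject's two samples are placed in TcB bands and the subject is classified
#' as *shifted* when the second timepoint lands in a strictly higher band
#' (low -> mid or higher). Downward band moves never count as a shift; they
#' are visible in `delta_tcb` only. Subjects with either timepoint outside
#' all bands are labelled `indeterminate`. TcB must be computed on the pooled
#' two-timepoint matrix so both timepoints share one scale -- per-timepoint
#' min-max rescaling would erase the shift.
#'
#' @param tcb [compute_tcb()] output over the pooled dataset.
#' @param metadata A [sample_table()] with exactly two timepoint levels (or
#'   restrict with `timepoints`); every subject needs one sample per
#'   timepoint, others are dropped with a warning.
#' @param cutoffs A [tcb_cutoffs()].
#' @param timepoints Optional length-2 character vector selecting/ordering the
#'   two timepoints.
#' @return Data frame with one row per subject: `subject_id`, `sample_t1`,
#'   `sample_t2`, `tcb_t1`, `tcb_t2`, `group_t1`, `group_t2`, `delta_tcb`,
#'   `shifted` (logical), `status` (`shifted`/`not_shifted`/`indeterminate`).
#' @export
paired_tcb_shift <- function(tcb, metadata, cutoffs = tcb_cutoffs(),
                             timepoints = NULL) {
  tps <- timepoints %||% levels(metadata$timepoint)
  if (length(tps) != 2L) {
    stop("paired shift analysis needs exactly 2 timepoints; got: ",
         paste(tps, collapse = ", "), call. = FALSE)
  }
  md <- metadata[as.character(metadata$timepoint) %in% tps, , drop = FALSE]
  grp <- assign_tcb_groups(tcb, cutoffs)
  rows <- list()
  for (subj in unique(md$subject_id)) {
    s1 <- md$sample_id[md$subject_id == subj & md$timepoint == tps[1L]]
    s2 <- md$sample_id[md$subject_id == subj & md$timepoint == tps[2L]]
    if (length(s1) != 1L || length(s2) != 1L) {
      warning(sprintf("subject '%s' lacks exactly one sample per timepoint; dropped",
                      subj), call. = FALSE)
      next
    }
    i1 <- match(s1, grp$sample_id); i2 <- match(s2, grp$sample_id)
    if (is.na(i1) || is.na(i2)) {
      warning(sprintf("subject '%s' has samples without TcB values; dropped",
                      subj), call. = FALSE)
      next
    }
    g1 <- as.character(grp$group[i1]); g2 <- as.character(grp$group[i2])
    if (g1 == "excluded" || g2 == "excluded") {
      status <- "indeterminate"; shifted <- FALSE
    } else {
      shifted <- band_rank(g2) > band_rank(g1)
      status <- if (shifted) "shifted" else "not_shifted"
    }
    rows[[subj]] <- data.frame(
      subject_id = subj, sample_t1 = s1, sample_t2 = s2,
      tcb_t1 = grp$tcb[i1], tcb_t2 = grp$tcb[i2],
      group_t1 = g1, group_t2 = g2,
      delta_tcb = grp$tcb[i2] - grp$tcb[i1],
      shifted = shifted, status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) stop("no subject with a complete sample pair", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Directional fold changes of higher-order category genes
#'
#' For every gene belonging to a higher-order category, computes the mean
#' paired log2 fold change (second minus first timepoint, averaged over
#' subjects), separately for the shifted subset, the non-shifted subset and
#' all paired subjects. This is the quantity displayed as directional
#' lollipop summaries comparing relapse against initial diagnosis with and
#' without a TcB shift.
#'
#' @param matrix Pooled log2-scale `tcb_matrix` containing both timepoints.
#' @param metadata A [sample_table()].
#' @param shifts Output of [paired_tcb_shift()].
#' @param sets A [gene_set_collection()] with a `category_map`.
#' @return Data frame with `category`, `gene_id`, `subset`
#'   (`shifted`/`not_shifted`/`all`), `log2fc`, `n_subjects`. Subsets with no
#'   subject are omitted.
#' @export
directional_foldchange <- function(matrix, metadata, shifts, sets) {
  assert_log2(matrix, "directional_foldchange")
  cmap <- sets$category_map
  if (is.null(cmap) || !length(cmap)) {
    stop("gene-set collection has no category map", call. = FALSE)
  }
  v <- em_values(matrix)
  # per-subject per-gene deltas, subjects in shift-table order
  d <- v[, shifts$sample_t2, drop = FALSE] - v[, shifts$sample_t1, drop = FALSE]
  colnames(d) <- shifts$subject_id
  subsets <- list(shifted = shifts$subject_id[shifts$status == "shifted"],
                  not_shifted = shifts$subject_id[shifts$status == "not_shifted"],
                  all = shifts$subject_id)
  cats <- unique(unname(cmap))
  rows <- list()
  for (cat in cats) {
    members <- unique(unlist(sets$sets[names(cmap)[cmap == cat]],
                             use.names = FALSE))
    hit <- intersect(members, rownames(v))
    if (!length(hit)) next
    for (sub in names(subsets)) {
      subj <- subsets[[sub]]
      if (!length(subj)) next
      fc <- rowMeans(d[hit, subj, drop = FALSE])
      rows[[paste(cat, sub)]] <- data.frame(
        category = cat, gene_id = hit, subset = sub,
        log2fc = unname(fc), n_subjects = length(subj),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) stop("no category gene present in the matrix", call. = FALSE)
  rownames(out) <- NULL
  out
}

# Gaussian KDE with boundary reflection at 0 and 1, evaluated on `grid`.
# Reflection keeps the probability mass of values confined to [0,1] inside
# the interval, so the density integrates to ~1 on the grid.
kde_reflect01 <- function(x, grid, bw) {
  stopifnot(bw > 0, length(x) > 0)
  n <- length(x)
  xa <- c(x, -x, 2 - x)
  xa <- xa[xa > -8 * bw & xa < 1 + 8 * bw]  # tails beyond 8 bw are negligible
  y <- numeric(length(grid))
  chunk <- 64L
  for (start in seq(1L, length(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(grid))
    z <- outer(grid[idx], xa, "-") / bw
    y[idx] <- rowSums(stats::dnorm(z)) / (n * bw)
  }
  y
}

#' Per-subject TcB courses and per-timepoint gene-shift densities
#'
#' For a multi-timepoint design, computes each subject's ordered TcB series
#' (on the pooled matrix, so all timepoints share one scale) with
#' per-interval deltas, and for each timepoint a Gaussian kernel density of
#' the global per-gene min-max values (`per_value` gene shift) on a fixed
#' grid over `[0, 1]`. The kernel is reflected at both boundaries; the
#' bandwidth defaults to Silverman's rule on each timepoint's values.
#'
#' @param matrix Pooled log2-scale `tcb_matrix` (subjects x timepoints as
#'   columns).
#' @param metadata A [sample_table()] with >= 2 timepoint levels; subjects
#'   with fewer than 2 timepoints are excluded with a warning.
#' @param cutoffs A [tcb_cutoffs()] used to annotate each sample's band.
#' @param grid_n Number of grid points on `[0, 1]` (default 512).
#' @param bw Kernel bandwidth; `NULL` (default) uses [stats::bw.nrd0()] per
#'   timepoint.
#' @param degenerate Passed to the per-gene min-max transform.
#' @return List of class `"tcb_course"`: `course` (data frame `subject_id`,
#'   `timepoint`, `sample_id`, `tcb`, `group`, `delta_tcb` -- delta from the
#'   previous timepoint, `NA` at the first) and `densities` (data frame
#'   `timepoint`, `x`, `density`).
#' @export
longitudinal_course <- function(matrix, metadata, cutoffs = tcb_cutoffs(),
                                grid_n = 512L, bw = NULL,
                                degenerate = c("error", "zeros")) {
  assert_log2(matrix, "longitudinal_course")
  tps <- levels(metadata$timepoint)
  if (length(tps) < 2L) stop("longitudinal analysis needs >= 2 timepoints",
                             call. = FALSE)
  tcb <- compute_tcb(matrix)
  grp <- assign_tcb_groups(tcb, cutoffs)
  md <- metadata[metadata$sample_id %in% colnames(matrix), , drop = FALSE]
  course <- list()
  for (subj in unique(md$subject_id)) {
    sm <- md[md$subject_id == subj, , drop = FALSE]
    sm <- sm[order(sm$timepoint), , drop = FALSE]
    if (nrow(sm) < 2L) {
      warning(sprintf("subject '%s' has a single timepoint; excluded", subj),
              call. = FALSE)
      next
    }
    idx <- match(sm$sample_id, grp$sample_id)
    tc <- grp$tcb[idx]
    course[[subj]] <- data.frame(
      subject_id = subj, timepoint = as.character(sm$timepoint),
      sample_id = sm$sample_id, tcb = tc,
      group = as.character(grp$group[idx]),
      delta_tcb = c(NA_real_, diff(tc)), stringsAsFactors = FALSE)
  }
  course <- do.call(rbind, unname(course))
  if (is.null(course)) stop("no subject with >= 2 timepoints", call. = FALSE)
  rownames(course) <- NULL

  pv <- compute_gene_shift(matrix, mode = "per_value", degenerate = degenerate)
  grid <- seq(0, 1, length.out = grid_n)
  dens <- list()
  for (tp in tps) {
    ids <- intersect(md$sample_id[as.character(md$timepoint) == tp],
                     colnames(pv))
    if (!length(ids)) next
    x <- as.vector(pv[, ids, drop = FALSE])
    b <- bw %||% stats::bw.nrd0(x)
    dens[[tp]] <- data.frame(timepoint = tp, x = grid,
                             density = kde_reflect01(x, grid, b),
                             stringsAsFactors = FALSE)
  }
  structure(list(course = course, densities = do.call(rbind, unname(dens))),
            class = "tcb_course")
}

#' @export
print.tcb_course <- function(x, ...) {
  cat(sprintf("<tcb_course> %d subjects, %d timepoints\n",
              length(unique(x$course$subject_id)),
              length(unique(x$course$timepoint))))
  invisible(x)
}
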