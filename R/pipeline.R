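#' Full pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. A resolved copy
#' is written as JSON next to every [run_pipeline()] output, and re-running
#' with that copy reproduces the outputs exactly.
#'
#' @param pseudocount Pseudocount for [log2_transform()] of raw matrices.
#' @param gene_shift_mode `"median"` or `"per_value"` (see
#'   [compute_gene_shift()]).
#' @param cutoffs A [tcb_cutoffs()] object or list coercible to one.
#' @param de A [de_config()].
#' @param de_pairs List of ordered band pairs to compare (default low/high,
#'   low/mid, mid/high).
#' @param min_group Minimum band size for group-wise tests.
#' @param r_pos,r_neg,corr_p,corr_top Correlation-screen thresholds (see
#'   [select_top_correlated()]).
#' @param enrich_p,enrich_fdr,blacklist Over-representation thresholds (see
#'   [hypergeometric_enrichment()]).
#' @param degenerate `"error"` or `"zeros"` for degenerate min-max ranges.
#' @param seed Recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return A list of class `"tcb_config"`.
#' @export
tcb_config <- function(pseudocount = 1,
                       gene_shift_mode = c("median", "per_value"),
                       cutoffs = tcb_cutoffs(),
                       de = de_config(),
                       de_pairs = list(c("low", "high"), c("low", "mid"),
                                       c("mid", "high")),
                       min_group = 3L,
                       r_pos = 0.75, r_neg = -0.75, corr_p = 1e-4,
                       corr_top = 50L,
                       enrich_p = 1e-4, enrich_fdr = 0.05,
                       blacklist = c("disease", "development"),
                       degenerate = c("error", "zeros"),
                       seed = 1L) {
  gene_shift_mode <- match.arg(gene_shift_mode)
  degenerate <- match.arg(degenerate)
  if (!inherits(cutoffs, "tcb_cutoffs")) cutoffs <- do.call(tcb_cutoffs, as.list(cutoffs))
  structure(list(pseudocount = pseudocount, gene_shift_mode = gene_shift_mode,
                 cutoffs = cutoffs, de = de, de_pairs = de_pairs,
                 min_group = min_group, r_pos = r_pos, r_neg = r_neg,
                 corr_p = corr_p, corr_top = corr_top, enrich_p = enrich_p,
                 enrich_fdr = enrich_fdr, blacklist = blacklist,
                 degenerate = degenerate, seed = seed),
            class = "tcb_config")
}

#' Run the whole burden pipeline on one dataset
#'
#' Chains every stage: (optional) log2 transform, TcB and gene shift, abacus
#' ordering, band stratification, between-band differential expression,
#' Spearman screening, over-representation and higher-order collapsing (when
#' gene sets are supplied), and paired/longitudinal trajectory analysis (when
#' metadata is supplied). Stages whose inputs are absent are skipped and
#' logged, not errors. All outputs are plain TSV plus a JSON run manifest;
#' the pipeline is deterministic, so identical inputs and config give
#' byte-identical outputs.
#'
#' @param matrix A `tcb_matrix`, or a path readable by
#'   [read_expression_matrix()].
#' @param out_dir Output directory (created if missing).
#' @param scale Scale of the matrix when `matrix` is a path.
#' @param orientation Orientation when `matrix` is a path.
#' @param metadata Optional [sample_table()] or TSV path.
#' @param sets Optional [gene_set_collection()] or GMT path.
#' @param category_map Optional named vector or TSV path (attached to
#'   `sets`).
#' @param config A [tcb_config()].
#' @return Invisibly, a list with the in-memory stage results and the vector
#'   of files written.
#' @export
run_pipeline <- function(matrix, out_dir, scale = c("log2", "raw"),
                         orientation = "genes_in_rows",
                         metadata = NULL, sets = NULL, category_map = NULL,
                         config = tcb_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  stage <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  if (is.character(matrix)) {
    matrix <- read_expression_matrix(matrix, orientation = orientation,
                                     scale = match.arg(scale))
  }
  if (is.character(metadata)) metadata <- read_sample_table(metadata)
  if (is.character(sets)) sets <- read_gmt(sets)
  if (!is.null(sets) && !is.null(category_map)) {
    if (is.character(category_map) && length(category_map) == 1L) {
      category_map <- read_category_map(category_map)
    }
    sets <- gene_set_collection(sets$sets, category_map = category_map)
  }
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table(df, path)
    files <<- c(files, path)
  }

  if (expr_scale(matrix) == "raw") {
    matrix <- log2_transform(matrix, pseudocount = config$pseudocount)
    stage("transform: log2(raw + %g)", config$pseudocount)
  }
  stage("input: %d genes x %d samples (log2)", nrow(matrix), ncol(matrix))

  tcb <- compute_tcb(matrix, degenerate = config$degenerate)
  emit(tcb, "tcb.tsv")
  gshift <- compute_gene_shift(matrix, mode = "median",
                               degenerate = config$degenerate)
  emit(gshift, "gene_shift.tsv")
  ordered <- abacus_order(matrix, tcb, gshift)
  write_expression_matrix(ordered, file.path(out_dir, "ordered_matrix.tsv"))
  files <- c(files, file.path(out_dir, "ordered_matrix.tsv"))
  stage("transform: tcb + gene shift computed, matrix abacus-ordered")

  groups <- assign_tcb_groups(tcb, config$cutoffs)
  emit(groups, "groups.tsv")
  cnt <- attr(groups, "counts")
  stage("stratify: low=%d mid=%d high=%d excluded=%d",
        cnt[["low"]], cnt[["mid"]], cnt[["high"]], cnt[["excluded"]])

  de_tables <- list()
  for (pair in config$de_pairs) {
    nm <- paste0(pair[2L], "_vs_", pair[1L])
    de <- withCallingHandlers(
      between_group_de(matrix, groups, pair = pair, config = config$de,
                       min_group = config$min_group),
      warning = function(w) {
        stage("de[%s]: %s", nm, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    de_tables[[nm]] <- de
    emit(de, paste0("de_", nm, ".tsv"))
    stage("de[%s]: %d genes tested, %d significant", nm, nrow(de),
          sum(de$significant))
  }

  corr <- tcb_gene_correlation(matrix, tcb)
  sel <- select_top_correlated(corr, r_pos = config$r_pos,
                               r_neg = config$r_neg, p_max = config$corr_p,
                               top_n = config$corr_top)
  emit(sel$records, "corr.tsv")
  stage("correlate: %d positive_top, %d negative_top",
        nrow(sel$positive), nrow(sel$negative))

  enrich <- NULL
  higher <- NULL
  if (!is.null(sets)) {
    main_de <- de_tables[[1L]]
    sig <- if (!is.null(main_de)) main_de$gene_id[main_de$significant] else character()
    enrich <- hypergeometric_enrichment(sig, rownames(matrix), sets,
                                        p_max = config$enrich_p,
                                        fdr_max = config$enrich_fdr,
                                        blacklist = config$blacklist)
    emit(enrich, "enrich.tsv")
    stage("enrich: %d sets tested, %d significant (list %d genes)",
          nrow(enrich), sum(enrich$significant), length(sig))
    if (!is.null(sets$category_map)) {
      higher <- suppressWarnings(
        collapse_to_higher_order(matrix, sets, groups))
      gm <- higher$group_medians
      if (!is.null(gm)) {
        emit(data.frame(category = rownames(gm), gm, check.names = FALSE,
                        stringsAsFactors = FALSE), "higher_order.tsv")
      }
      emit(data.frame(category = rownames(higher$sample_means),
                      higher$sample_means, check.names = FALSE,
                      stringsAsFactors = FALSE), "higher_order_samples.tsv")
      stage("collapse: %d categories", nrow(higher$sample_means))
    } else {
      stage("collapse: skipped (no category map)")
    }
  } else {
    stage("enrich: skipped (no gene sets)")
  }

  shifts <- NULL
  course <- NULL
  if (!is.null(metadata)) {
    tps <- levels(metadata$timepoint)
    if (length(tps) == 2L) {
      shifts <- suppressWarnings(
        paired_tcb_shift(tcb, metadata, cutoffs = config$cutoffs))
      emit(shifts, "shifts.tsv")
      stage("shift: %d subjects, %d shifted, %d indeterminate",
            nrow(shifts), sum(shifts$status == "shifted"),
            sum(shifts$status == "indeterminate"))
      if (!is.null(sets) && !is.null(sets$category_map)) {
        dfc <- directional_foldchange(matrix, metadata, shifts, sets)
        emit(dfc, "directional_fc.tsv")
        stage("directional_fc: %d records", nrow(dfc))
      }
    } else if (length(tps) > 2L) {
      course <- suppressWarnings(
        longitudinal_course(matrix, metadata, cutoffs = config$cutoffs,
                            degenerate = config$degenerate))
      emit(course$course, "course.tsv")
      emit(course$densities, "gene_shift_density.tsv")
      stage("course: %d subjects over %d timepoints",
            length(unique(course$course$subject_id)), length(tps))
    }
  } else {
    stage("trajectory: skipped (no metadata)")
  }

  cfg_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(config_as_list(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, cfg_path)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files <- c(files, file.path(out_dir, "run_log.txt"))
  invisible(list(tcb = tcb, gene_shift = gshift, groups = groups,
                 de = de_tables, correlation = sel, enrichment = enrich,
                 higher_order = higher, shifts = shifts, course = course,
                 files = files, log = log_lines))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$cutoffs <- unclass(out$cutoffs)
  out
}
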