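new_truth <- function(samples, genes, seed, extra = list()) {
  structure(c(list(samples = samples, genes = genes, seed = seed), extra),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d samples, %d genes (up %d / down %d), seed %d\n",
              nrow(x$samples), nrow(x$genes),
              sum(x$genes$program == "up"), sum(x$genes$program == "down"),
              x$seed))
  invisible(x)
}

# Plant program genes and bundle them into a small GMT-like collection:
# up-program genes emulate an ECM-like module rising with burden; down
# genes are spread over cell-cycle / translation / TCA-ETC / transcription
# modules that decline as burden grows.
plant_programs <- function(n_genes, frac_up, frac_down) {
  stopifnot(frac_up >= 0, frac_down >= 0)
  if (frac_up + frac_down > 1) {
    stop("frac_up + frac_down must be <= 1", call. = FALSE)
  }
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  n_up <- round(frac_up * n_genes)
  n_down <- round(frac_down * n_genes)
  program <- rep("null", n_genes)
  program[seq_len(n_up)] <- "up"
  if (n_down > 0L) program[n_up + seq_len(n_down)] <- "down"
  sign <- c(up = 1, null = 0, down = -1)[program]
  module <- rep("none", n_genes)
  sets <- list()
  cmap <- character()
  if (n_up > 0L) {
    sets[["ECM_LIKE"]] <- gene_ids[program == "up"]
    cmap["ECM_LIKE"] <- "ECM"
    module[program == "up"] <- "ECM_LIKE"
  }
  down_modules <- c(CELLCYCLE_LIKE = "cell_cycle", TRANSLATION_LIKE = "translation",
                    TCA_ETC_LIKE = "TCA_ETC", TRANSCRIPTION_LIKE = "transcription")
  if (n_down > 0L) {
    idx_down <- which(program == "down")
    slot <- rep_len(seq_along(down_modules), length(idx_down))
    for (k in seq_along(down_modules)) {
      g <- gene_ids[idx_down[slot == k]]
      if (!length(g)) next
      nm <- names(down_modules)[k]
      sets[[nm]] <- g
      cmap[nm] <- down_modules[[k]]
      module[match(g, gene_ids)] <- nm
    }
  }
  n_null_pick <- min(50L, sum(program == "null"))
  if (n_null_pick >= 1L) {
    sets[["RANDOM_NULL_SET"]] <- gene_ids[program == "null"][seq_len(n_null_pick)]
    cmap["RANDOM_NULL_SET"] <- "control"
  }
  list(gene_ids = gene_ids, program = program, sign = unname(sign),
       module = module,
       sets = gene_set_collection(sets, category_map = cmap))
}

#' Synthetic progression dataset with planted gene programs
#'
#' Emulates a cross-sectional tumor cohort ordered along a hidden progression
#' axis. Sample `i` receives an index `x_i` equally spaced on `[0, 1]` (so
#' every burden band is occupied deterministically), and each log2 value is
#' `baseline_g + sign_g * slope * x_i + global_gain * x_i + N(0, noise_sd)`,
#' where `sign_g` is +1 for up-program genes, -1 for down-program genes and 0
#' for null genes. The global gain drives the per-sample expression sum, so
#' the computed TcB recovers the hidden axis; program genes additionally rise
#' or fall along it. Noise is Gaussian on the log2 scale, where the method
#' operates.
#'
#' @param n_samples,n_genes Dataset dimensions (defaults 120 x 2000).
#' @param frac_up,frac_down Fractions of up/down program genes (default 0.05
#'   each); must sum to <= 1.
#' @param baseline_mean,baseline_sd Per-gene baselines drawn from
#'   `N(baseline_mean, baseline_sd)` (defaults 6 and 1.5, typical log2 TPM).
#' @param slope Program amplitude over the full axis (default 2).
#' @param global_gain Global log2 gain over the full axis applied to every
#'   gene (default 1).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.5).
#' @param seed RNG seed (default 7); output is bit-reproducible given a seed.
#' @return List with `matrix` (log2 `tcb_matrix`), `truth`
#'   (`synthetic_truth`: hidden index per sample, program and module per
#'   gene) and `sets` (bundled [gene_set_collection()] with category map).
#' @export
generate_progression_dataset <- function(n_samples = 120L, n_genes = 2000L,
                                         frac_up = 0.05, frac_down = 0.05,
                                         baseline_mean = 6, baseline_sd = 1.5,
                                         slope = 2, global_gain = 1,
                                         noise_sd = 0.5, seed = 7L) {
  stopifnot(n_samples >= 2L, n_genes >= 2L, noise_sd >= 0)
  set.seed(seed)
  pp <- plant_programs(n_genes, frac_up, frac_down)
  x <- seq(0, 1, length.out = n_samples)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  signal <- outer(pp$sign * slope + global_gain, x)
  vals <- baseline + signal +
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples)
  dimnames(vals) <- list(pp$gene_ids, sample_ids)
  list(matrix = expression_matrix(vals, scale = "log2"),
       truth = new_truth(
         samples = data.frame(sample_id = sample_ids, progression_index = x,
                              stringsAsFactors = FALSE),
         genes = data.frame(gene_id = pp$gene_ids, program = pp$program,
                            module = pp$module, stringsAsFactors = FALSE),
         seed = seed),
       sets = pp$sets)
}

#' Synthetic paired initial/relapse dataset with designated shifters
#'
#' Emulates a two-timepoint relapse cohort. Every subject contributes an
#' `initial` and a `relapse` sample; a designated fraction of subjects are
#' "shifters". At the second timepoint shifters receive an additive global
#' log2 gain of `shift_gain` on every gene plus program progression (their
#' hidden index advances by `program_delta`); non-shifters receive fresh
#' noise only. With `shift_gain = 0` the classifier therefore sees only
#' noise and detection sits at chance. The default `shift_gain = 0.5` is the
#' strong preset: the global sum moves by `n_genes * shift_gain`, far beyond
#' the noise of the sum, so shifters jump bands.
#'
#' @param n_subjects Number of subjects (default 40; must be >= 4 so the
#'   bands are occupied).
#' @param frac_shifters Fraction of subjects planted as shifters (default
#'   0.5), strictly between 0 and 1.
#' @param shift_gain Additive per-gene log2 gain at the second timepoint for
#'   shifters (default 0.5).
#' @param program_delta Advance of the shifters' hidden index at the second
#'   timepoint, moving program genes (default 0.5).
#' @param t1_spread Width of the baseline index range `[0, t1_spread]` that
#'   subjects occupy at the first timepoint (default 0.1).
#' @inheritParams generate_progression_dataset
#' @return List with `matrix` (pooled log2 `tcb_matrix`, 2 x n_subjects
#'   columns), `metadata` ([sample_table()] with timepoints
#'   `initial`/`relapse`), `truth` (per-subject `shifter` flag in
#'   `$subjects`), and `sets`.
#' @export
generate_paired_dataset <- function(n_subjects = 40L, frac_shifters = 0.5,
                                    shift_gain = 0.5, n_genes = 2000L,
                                    frac_up = 0.05, frac_down = 0.05,
                                    baseline_mean = 6, baseline_sd = 1.5,
                                    slope = 2, global_gain = 1,
                                    noise_sd = 0.5, program_delta = 0.5,
                                    t1_spread = 0.1, seed = 7L) {
  if (n_subjects < 4L) stop("n_subjects must be >= 4", call. = FALSE)
  if (frac_shifters <= 0 || frac_shifters >= 1) {
    stop("frac_shifters must be strictly between 0 and 1", call. = FALSE)
  }
  set.seed(seed)
  pp <- plant_programs(n_genes, frac_up, frac_down)
  subjects <- sprintf("P%03d", seq_len(n_subjects))
  n_shift <- max(1L, round(frac_shifters * n_subjects))
  shifter <- sample(rep(c(TRUE, FALSE), c(n_shift, n_subjects - n_shift)))
  x1 <- seq(0, t1_spread, length.out = n_subjects)
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  make_tp <- function(x_prog, x_global, extra_gain) {
    baseline + outer(pp$sign * slope, x_prog) + outer(rep(global_gain, n_genes), x_global) +
      matrix(rep(extra_gain, each = n_genes), n_genes, n_subjects) +
      matrix(stats::rnorm(n_genes * n_subjects, 0, noise_sd), n_genes, n_subjects)
  }
  v1 <- make_tp(x1, x1, rep(0, n_subjects))
  v2 <- make_tp(x1 + program_delta * shifter, x1, shift_gain * shifter)
  s1 <- paste0(subjects, "_initial")
  s2 <- paste0(subjects, "_relapse")
  vals <- cbind(v1, v2)
  dimnames(vals) <- list(pp$gene_ids, c(s1, s2))
  metadata <- sample_table(
    data.frame(sample_id = c(s1, s2),
               subject_id = rep(subjects, 2L),
               timepoint = rep(c("initial", "relapse"), each = n_subjects),
               stringsAsFactors = FALSE),
    timepoints = c("initial", "relapse"))
  truth <- new_truth(
    samples = data.frame(sample_id = c(s1, s2),
                         progression_index = c(x1, x1 + program_delta * shifter),
                         stringsAsFactors = FALSE),
    genes = data.frame(gene_id = pp$gene_ids, program = pp$program,
                       module = pp$module, stringsAsFactors = FALSE),
    seed = seed,
    extra = list(subjects = data.frame(subject_id = subjects,
                                       shifter = shifter,
                                       stringsAsFactors = FALSE)))
  list(matrix = expression_matrix(vals, scale = "log2"),
       metadata = metadata, truth = truth, sets = pp$sets)
}

#' Synthetic longitudinal dataset with treatment reversal
#'
#' Emulates a small interventional time course: subjects start at a high
#' hidden burden index and the index decays by `reversal_strength` per
#' interval under treatment, so global expression and up-program genes
#' decline while down-program genes recover symmetrically. With
#' `reversal_strength = 0` the courses are flat.
#'
#' @param n_subjects Number of subjects (default 6).
#' @param n_timepoints Number of timepoints per subject (default 3, >= 2).
#' @param reversal_strength Decay of the hidden index per interval
#'   (default 0.25).
#' @param start_range Range the subjects' initial indices occupy (default
#'   `c(0.6, 1)`).
#' @inheritParams generate_progression_dataset
#' @return List with `matrix` (pooled log2 `tcb_matrix`), `metadata`
#'   (timepoints `t1..tk`), `truth` (hidden index per sample) and `sets`.
#' @export
generate_longitudinal_reversal <- function(n_subjects = 6L, n_timepoints = 3L,
                                           reversal_strength = 0.25,
                                           n_genes = 2000L,
                                           frac_up = 0.05, frac_down = 0.05,
                                           baseline_mean = 6, baseline_sd = 1.5,
                                           slope = 2, global_gain = 1,
                                           noise_sd = 0.5,
                                           start_range = c(0.6, 1), seed = 7L) {
  stopifnot(n_subjects >= 1L, reversal_strength >= 0)
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2", call. = FALSE)
  set.seed(seed)
  pp <- plant_programs(n_genes, frac_up, frac_down)
  subjects <- sprintf("D%02d", seq_len(n_subjects))
  tps <- paste0("t", seq_len(n_timepoints))
  x0 <- if (n_subjects == 1L) mean(start_range) else
    seq(start_range[1L], start_range[2L], length.out = n_subjects)
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  grid <- expand.grid(subject = seq_len(n_subjects),
                      tp = seq_len(n_timepoints))
  x <- pmax(x0[grid$subject] - reversal_strength * (grid$tp - 1L), 0)
  sample_ids <- paste0(subjects[grid$subject], "_", tps[grid$tp])
  vals <- baseline + outer(pp$sign * slope + global_gain, x) +
    matrix(stats::rnorm(n_genes * length(x), 0, noise_sd), n_genes, length(x))
  dimnames(vals) <- list(pp$gene_ids, sample_ids)
  metadata <- sample_table(
    data.frame(sample_id = sample_ids,
               subject_id = subjects[grid$subject],
               timepoint = tps[grid$tp], stringsAsFactors = FALSE),
    timepoints = tps)
  truth <- new_truth(
    samples = data.frame(sample_id = sample_ids, progression_index = x,
                         stringsAsFactors = FALSE),
    genes = data.frame(gene_id = pp$gene_ids, program = pp$program,
                       module = pp$module, stringsAsFactors = FALSE),
    seed = seed)
  list(matrix = expression_matrix(vals, scale = "log2"),
       metadata = metadata, truth = truth, sets = pp$sets)
}

#' Write a gene-set collection in GMT format
#'
#' @param sets A [gene_set_collection()].
#' @param path Output `.gmt` path.
#' @param catmap_path Optional path for the category-map TSV.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, catmap_path = NULL) {
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, "synthetic", sets$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  if (!is.null(catmap_path) && !is.null(sets$category_map)) {
    write_table(data.frame(set_name = names(sets$category_map),
                           category = unname(sets$category_map),
                           stringsAsFactors = FALSE), catmap_path)
  }
  invisible(path)
}
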