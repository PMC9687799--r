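shift_fixture <- function(tcb_t1, tcb_t2) {
  n <- length(tcb_t1)
  subjects <- sprintf("P%02d", seq_len(n))
  md <- tiny_paired_meta(subjects)
  tcb <- data.frame(sample_id = md$sample_id, tcb = c(tcb_t1, tcb_t2))
  list(md = md, tcb = tcb, subjects = subjects)
}

test_that("upward band moves are shifts, same-band and downward moves are not", {
  fx <- shift_fixture(c(0.10, 0.10, 0.50), c(0.50, 0.20, 0.10))
  sh <- paired_tcb_shift(fx$tcb, fx$md)
  expect_identical(sh$shifted, c(TRUE, FALSE, FALSE))
  expect_identical(sh$status, c("shifted", "not_shifted", "not_shifted"))
  expect_equal(sh$delta_tcb, c(0.4, 0.1, -0.4))
})

test_that("samples in the cutoff gaps make a subject indeterminate", {
  fx <- shift_fixture(c(0.30, 0.10), c(0.80, 0.30))
  sh <- paired_tcb_shift(fx$tcb, fx$md)
  expect_identical(sh$status, c("indeterminate", "indeterminate"))
  expect_false(any(sh$shifted))
})

test_that("subjects missing a timepoint are dropped with a warning", {
  fx <- shift_fixture(c(0.1, 0.1), c(0.9, 0.9))
  md <- fx$md[-2, ]  # P02 loses its initial sample
  expect_warning(sh <- paired_tcb_shift(fx$tcb, md), "P02")
  expect_identical(sh$subject_id, "P01")
})

test_that("classification agrees with a direct cutoff lookup on random pairs", {
  set.seed(23)
  t1 <- runif(60); t2 <- runif(60)
  fx <- shift_fixture(t1, t2)
  sh <- paired_tcb_shift(fx$tcb, fx$md)
  band_of <- function(x) {
    ifelse(x <= 0.25, 1L, ifelse(x >= 0.375 & x <= 0.625, 2L,
                                 ifelse(x >= 0.75, 3L, NA_integer_)))
  }
  b1 <- band_of(t1); b2 <- band_of(t2)
  expect_identical(sh$shifted, !is.na(b1) & !is.na(b2) & b2 > b1)
})

test_that("directional fold changes average paired deltas per subset", {
  subjects <- sprintf("P%02d", 1:5)
  md <- tiny_paired_meta(subjects)
  # gene Gup gains 1, 2, 3 in shifted subjects, 0 elsewhere; Gflat unchanged
  v1 <- rbind(Gup = rep(5, 5), Gflat = rep(3, 5), Gother = 1:5)
  v2 <- rbind(Gup = 5 + c(1, 2, 3, 0, 0), Gflat = rep(3, 5), Gother = 1:5)
  vals <- cbind(v1, v2); colnames(vals) <- md$sample_id
  em <- expression_matrix(vals, "log2")
  shifts <- data.frame(subject_id = subjects,
                       sample_t1 = md$sample_id[1:5],
                       sample_t2 = md$sample_id[6:10],
                       status = c("shifted", "shifted", "shifted",
                                  "not_shifted", "not_shifted"),
                       stringsAsFactors = FALSE)
  sets <- gene_set_collection(list(S = c("Gup", "Gflat")),
                              category_map = c(S = "cat"))
  fc <- directional_foldchange(em, md, shifts, sets)
  get <- function(g, s) fc$log2fc[fc$gene_id == g & fc$subset == s]
  expect_equal(get("Gup", "shifted"), 2)       # mean of 1, 2, 3
  expect_equal(get("Gup", "not_shifted"), 0)
  expect_equal(get("Gflat", "all"), 0)
  expect_identical(unique(fc$n_subjects[fc$subset == "shifted"]), 3L)
})

test_that("a dataset compared against itself has identically zero fold change", {
  subjects <- sprintf("P%02d", 1:4)
  md <- tiny_paired_meta(subjects)
  half <- matrix(rnorm(40, 6), 10, 4,
                 dimnames = list(sprintf("G%02d", 1:10), md$sample_id[1:4]))
  vals <- cbind(half, half); colnames(vals) <- md$sample_id
  em <- expression_matrix(vals, "log2")
  shifts <- data.frame(subject_id = subjects, sample_t1 = md$sample_id[1:4],
                       sample_t2 = md$sample_id[5:8],
                       status = rep("not_shifted", 4), stringsAsFactors = FALSE)
  sets <- gene_set_collection(list(S = rownames(em)),
                              category_map = c(S = "cat"))
  fc <- directional_foldchange(em, md, shifts, sets)
  expect_true(all(fc$log2fc == 0))
})

test_that("longitudinal courses track pooled TcB and their densities normalise", {
  l <- generate_longitudinal_reversal(n_subjects = 4, n_genes = 300,
                                      noise_sd = 0, seed = 3)
  lc <- longitudinal_course(l$matrix, l$metadata)
  # noiseless reversal: every within-subject delta is negative
  expect_true(all(lc$course$delta_tcb[!is.na(lc$course$delta_tcb)] < 0))
  # per-timepoint density integrates to 1 on the grid
  for (tp in unique(lc$densities$timepoint)) {
    d <- lc$densities[lc$densities$timepoint == tp, ]
    integral <- sum((d$density[-1] + d$density[-nrow(d)]) / 2 * diff(d$x))
    expect_equal(integral, 1, tolerance = 1e-3)
  }
})

test_that("a global halving of expression lowers every subject's TcB", {
  set.seed(41)
  subjects <- sprintf("P%02d", 1:5)
  md <- tiny_paired_meta(subjects, "t1", "t2")
  base <- matrix(rnorm(200 * 5, 8, 1), 200, 5)
  vals <- cbind(base, base - 1)  # halving on the log2 scale
  dimnames(vals) <- list(sprintf("G%03d", 1:200), md$sample_id)
  em <- expression_matrix(vals, "log2")
  tcb <- compute_tcb(em)
  t1 <- tcb$tcb[match(md$sample_id[1:5], tcb$sample_id)]
  t2 <- tcb$tcb[match(md$sample_id[6:10], tcb$sample_id)]
  expect_true(all(t2 < t1))
})

test_that("identical timepoints give flat courses and identical densities", {
  subjects <- sprintf("P%02d", 1:3)
  tps <- c("t1", "t2", "t3")
  grid <- expand.grid(s = subjects, t = tps)
  ids <- paste0(grid$s, "_", grid$t)
  md <- sample_table(data.frame(sample_id = ids, subject_id = grid$s,
                                timepoint = grid$t), timepoints = tps)
  set.seed(2)
  block <- matrix(rnorm(50 * 3, 6), 50, 3)
  vals <- cbind(block, block, block)
  # give the three subjects different levels so TcB is non-degenerate
  vals <- vals + rep(c(0, 0.5, 1), times = 3)[col(vals)]
  dimnames(vals) <- list(sprintf("G%02d", 1:50), ids)
  em <- expression_matrix(vals, "log2")
  lc <- longitudinal_course(em, md)
  expect_true(all(lc$course$delta_tcb[!is.na(lc$course$delta_tcb)] == 0))
  d <- split(lc$densities$density, lc$densities$timepoint)
  expect_equal(d$t1, d$t2)
  expect_equal(d$t1, d$t3)
})
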