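make_groups <- function(ids_a, ids_b) {
  data.frame(sample_id = c(ids_a, ids_b),
             tcb = c(rep(0.1, length(ids_a)), rep(0.9, length(ids_b))),
             group = factor(rep(c("low", "high"), c(length(ids_a), length(ids_b))),
                            levels = c("low", "mid", "high", "excluded")))
}

test_that("between-group effects and flags follow their definitions", {
  set.seed(5)
  n <- 4
  ids_a <- paste0("a", 1:n); ids_b <- paste0("b", 1:n)
  # gene 1 identical in both groups; gene 2 means 2 vs 4 with tiny variance
  g1 <- rep(c(1, 2, 3, 4), 2)
  g2 <- c(2, 2.001, 1.999, 2, 4, 4.001, 3.999, 4)
  vals <- rbind(g1, g2)
  em <- expression_matrix(matrix(vals, 2, 2 * n,
                                 dimnames = list(c("G1", "G2"), c(ids_a, ids_b))),
                          "log2")
  de <- between_group_de(em, make_groups(ids_a, ids_b))
  expect_equal(de$log2fc[de$gene_id == "G1"], 0)
  expect_false(de$significant[de$gene_id == "G1"])
  expect_equal(de$log2fc[de$gene_id == "G2"], 2, tolerance = 1e-3)
  expect_true(de$significant[de$gene_id == "G2"])
  expect_identical(unique(de$comparison), "high_vs_low")
})

test_that("log2fc is antisymmetric in the pair order", {
  em <- rand_em(30, 12, seed = 9)
  grp <- make_groups(colnames(em)[1:6], colnames(em)[7:12])
  d1 <- between_group_de(em, grp, pair = c("low", "high"))
  d2 <- between_group_de(em, grp, pair = c("high", "low"))
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
})

test_that("the vectorised Welch test agrees with stats::t.test", {
  set.seed(13)
  em <- rand_em(50, 15, seed = 13)
  ids_a <- colnames(em)[1:7]; ids_b <- colnames(em)[8:15]
  de <- between_group_de(em, make_groups(ids_a, ids_b),
                         config = de_config(p = 0.05, fdr = 0.5))
  v <- unclass(em)[, ]
  ref <- vapply(seq_len(nrow(v)), function(i) {
    t.test(v[i, ids_b], v[i, ids_a])$p.value
  }, numeric(1))
  expect_equal(de$p_value, ref, tolerance = 1e-12)
})

test_that("zero-variance genes get the convention p-values", {
  ids_a <- paste0("a", 1:3); ids_b <- paste0("b", 1:3)
  vals <- rbind(rep(1, 6), rep(c(1, 2), each = 3), c(1, 1, 1, 1, 1, 2))
  em <- expression_matrix(matrix(vals, 3, 6,
                                 dimnames = list(paste0("G", 1:3), c(ids_a, ids_b))),
                          "log2")
  de <- between_group_de(em, make_groups(ids_a, ids_b))
  expect_equal(de$p_value[1], 1)  # flat and equal
  expect_equal(de$p_value[2], 0)  # flat, different means
})

test_that("undersized groups are skipped with a warning", {
  em <- rand_em(5, 5, seed = 2)
  grp <- make_groups(colnames(em)[1:2], colnames(em)[3:5])
  expect_warning(de <- between_group_de(em, grp), "fewer than 3")
  expect_identical(nrow(de), 0L)
})

test_that("Mann-Whitney option matches stats::wilcox.test", {
  em <- rand_em(20, 12, seed = 21)
  grp <- make_groups(colnames(em)[1:6], colnames(em)[7:12])
  de <- between_group_de(em, grp, config = de_config(test = "wilcoxon"))
  v <- unclass(em)[, ]
  ref <- vapply(seq_len(nrow(v)), function(i) {
    wilcox.test(v[i, 1:6], v[i, 7:12])$p.value
  }, numeric(1))
  expect_equal(de$p_value, ref, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  set.seed(31)
  for (m in c(10, 137, 1000)) {
    p <- runif(m)^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # and the DE table's fdr column is BH of its p column
  em <- rand_em(40, 12, seed = 8)
  grp <- make_groups(colnames(em)[1:6], colnames(em)[7:12])
  de <- between_group_de(em, grp)
  expect_equal(de$fdr, bh_oracle(de$p_value), tolerance = 1e-12)
})

test_that("within-group deviation references the group median", {
  ids <- paste0("s", 1:5)
  vals <- rbind(rep(2, 5), c(1, 2, 3, 4, 10), c(1, 2, 3, 4, 5))
  em <- expression_matrix(matrix(vals, 3, 5,
                                 dimnames = list(paste0("G", 1:3), ids)), "log2")
  grp <- data.frame(sample_id = ids, tcb = rep(0.1, 5),
                    group = factor(rep("low", 5),
                                   levels = c("low", "mid", "high", "excluded")))
  w <- within_group_deviation(em, grp, "low")
  expect_equal(w$log2fc[1], 0)        # constant gene
  expect_equal(w$p_value[1], 1)
  expect_equal(w$log2fc[2], 1.0)      # reference 3, mean deviation 1
  expect_equal(w$log2fc[3], 0)        # symmetric about its median
})

test_that("external DE tables are validated and re-flagged", {
  p <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("A", "B", "C"), log2fc = c(2, -0.1, 1.5),
                   p_value = c(1e-6, 0.2, 1e-5))
  write_table(df, p)
  de <- import_external_de(p, de_config(fc = 1.25, p = 1e-3, fdr = 0.05))
  expect_equal(de$fdr, bh_oracle(df$p_value), tolerance = 1e-12)
  expect_identical(de$significant, c(TRUE, FALSE, TRUE))

  df$fdr <- c(0.001, 0.9, 0.2)
  write_table(df, p)
  de2 <- import_external_de(p, de_config(fc = 1.25, p = 1e-3, fdr = 0.05))
  expect_identical(de2$significant, c(TRUE, FALSE, FALSE))  # provided fdr used

  df$fdr <- NULL; df$p_value[1] <- 1.5
  write_table(df, p)
  expect_error(import_external_de(p), "outside \\[0, 1\\]")
  write_table(df[, c("gene_id", "log2fc")], p)
  expect_error(import_external_de(p), "p_value")
})
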