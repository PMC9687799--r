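# exhaustive oracle: over all possible lists of the same size drawn from the
# universe, the fraction whose overlap with the set reaches the observed one
enum_tail_p <- function(universe, set, list_size, observed) {
  draws <- combn(universe, list_size)
  mean(apply(draws, 2, function(d) length(intersect(d, set)) >= observed))
}

test_that("a fully overlapping small instance matches the combinatorial value", {
  u <- paste0("g", 1:20)
  sets <- gene_set_collection(list(S = u[1:5]))
  e <- hypergeometric_enrichment(u[1:5], u, sets)
  expect_equal(e$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(e$overlap, 5L)
})

test_that("hypergeometric tail equals exhaustive enumeration on small universes", {
  set.seed(19)
  for (i in 1:12) {
    n_u <- sample(6:15, 1)
    u <- paste0("g", seq_len(n_u))
    set_g <- sample(u, sample(2:(n_u - 1), 1))
    list_g <- sample(u, sample(2:(n_u - 1), 1))
    sets <- gene_set_collection(list(S = set_g))
    e <- hypergeometric_enrichment(list_g, u, sets)
    expect_equal(e$p_value, enum_tail_p(u, set_g, length(list_g), e$overlap),
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs follow the documented conventions", {
  u <- paste0("g", 1:10)
  sets <- gene_set_collection(list(A = u[1:4], B = c("zz1", "zz2")))
  # empty list: every set reported with p = 1
  e <- hypergeometric_enrichment(character(), u, sets)
  expect_equal(e$p_value, c(1, 1))
  expect_identical(nrow(e), 2L)
  # set disjoint from universe: size 0 after intersection, p = 1
  e2 <- hypergeometric_enrichment(u[1:3], u, sets)
  expect_identical(e2$set_size[e2$set_name == "B"], 0L)
  expect_equal(e2$p_value[e2$set_name == "B"], 1)
  # zero overlap with a real set is near 1, never significant
  sets3 <- gene_set_collection(list(A = u[1:4]))
  e3 <- hypergeometric_enrichment(u[5:7], u, sets3)
  expect_identical(e3$overlap, 0L)
  expect_gt(e3$p_value, 0.5)
  # list outside universe and empty universe are errors
  expect_error(hypergeometric_enrichment(c("nope"), u, sets), "outside")
  expect_error(hypergeometric_enrichment("a", character(), sets), "empty universe")
})

test_that("blacklisted ambiguous categories are not tested", {
  u <- paste0("g", 1:10)
  sets <- gene_set_collection(list(Disease = u[1:4], Core = u[5:8]))
  e <- hypergeometric_enrichment(u[1:4], u, sets, blacklist = "disease")
  expect_identical(e$set_name, "Core")
})

test_that("overlaps of disjoint sets cannot exceed the list size", {
  u <- paste0("g", 1:30)
  sets <- gene_set_collection(list(A = u[1:10], B = u[11:20], C = u[21:30]))
  set.seed(3)
  lst <- sample(u, 12)
  e <- hypergeometric_enrichment(lst, u, sets)
  expect_identical(sum(e$overlap), 12L)
})

test_that("higher-order collapsing averages members and medians bands", {
  ids <- paste0("s", 1:4)
  vals <- rbind(G1 = c(2, 2, 8, 8), G2 = c(4, 4, 10, 10), G3 = c(0, 1, 2, 3))
  colnames(vals) <- ids
  em <- expression_matrix(vals, "log2")
  sets <- gene_set_collection(list(P1 = c("G1", "G2"), P2 = "G3",
                                   P3 = c("G1", "ABSENT")),
                              category_map = c(P1 = "catA", P2 = "catB",
                                               P3 = "catA"))
  grp <- data.frame(sample_id = ids, tcb = c(0, 0.1, 0.9, 1),
                    group = factor(c("low", "low", "high", "high"),
                                   levels = c("low", "mid", "high", "excluded")))
  hs <- collapse_to_higher_order(em, sets, grp)
  expect_equal(unname(hs$sample_means["catA", ]), c(3, 3, 9, 9))  # union G1,G2
  expect_equal(unname(hs$sample_means["catB", ]), c(0, 1, 2, 3))
  expect_equal(unname(hs$group_medians["catA", ]), c(low = 3, high = 9),
               ignore_attr = TRUE)
  expect_identical(hs$coverage$matched[hs$coverage$category == "catA"], 2L)
  # single-gene category equals that gene's row
  expect_equal(unname(hs$sample_means["catB", ]), unname(vals["G3", ]))
})

test_that("collapsing commutes with sample subsetting", {
  em <- rand_em(12, 8, seed = 14)
  sets <- gene_set_collection(list(P = rownames(em)[1:5]),
                              category_map = c(P = "cat"))
  keep <- colnames(em)[c(1, 3, 5, 7)]
  full <- collapse_to_higher_order(em, sets)
  sub <- collapse_to_higher_order(em[, keep], sets)
  expect_equal(sub$sample_means[, keep], full$sample_means[, keep])
})

test_that("a category with no matched gene is dropped with a warning", {
  em <- rand_em(4, 4, seed = 1)
  sets <- gene_set_collection(list(P = "NOT_THERE", Q = rownames(em)[1:2]),
                              category_map = c(P = "ghost", Q = "real"))
  expect_warning(hs <- collapse_to_higher_order(em, sets), "ghost")
  expect_identical(rownames(hs$sample_means), "real")
})
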