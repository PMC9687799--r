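# small in-code fixtures shared across test files

make_em <- function(values, n_genes, n_samples, scale = "log2",
                    genes = sprintf("G%02d", seq_len(n_genes)),
                    samples = sprintf("S%02d", seq_len(n_samples))) {
  expression_matrix(matrix(values, n_genes, n_samples,
                           dimnames = list(genes, samples)), scale = scale)
}

rand_em <- function(n_genes, n_samples, seed = 1, mean = 6, sd = 1) {
  set.seed(seed)
  make_em(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples)
}

# brute-force min-max oracle, written independently of median_shift()
minmax_oracle <- function(v) (v - min(v)) / (max(v) - min(v))

# brute-force Benjamini-Hochberg: sort, p * m / rank, cumulative minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

tiny_paired_meta <- function(subjects, t1 = "initial", t2 = "relapse") {
  sample_table(data.frame(
    sample_id = c(paste0(subjects, "_", t1), paste0(subjects, "_", t2)),
    subject_id = rep(subjects, 2L),
    timepoint = rep(c(t1, t2), each = length(subjects)),
    stringsAsFactors = FALSE), timepoints = c(t1, t2))
}
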