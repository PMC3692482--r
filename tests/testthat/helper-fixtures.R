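# Small in-code fixtures shared across test files.

random_states <- function(n, levels = c(-1L, 0L, 1L)) {
  sample(levels, n, replace = TRUE)
}

# A tiny genotype/expression pair with strong planted structure:
# marker snpA drives genes g1, g2 additively; g3..g6 are noise.
tiny_dataset <- function(n = 60, seed = 7) {
  withr::with_seed(seed, {
    g <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    g2 <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    expr <- rbind(
      g1 = 8 + 3 * (g - 2) + rnorm(n, 0, 1),
      g2 = 10 - 3 * (g - 2) + rnorm(n, 0, 1),
      g3 = 7 + rnorm(n, 0, 1),
      g4 = 9 + rnorm(n, 0, 1),
      g5 = 11 + rnorm(n, 0, 1),
      g6 = 6 + rnorm(n, 0, 1)
    )
    samples <- sprintf("S%02d", seq_len(n))
    colnames(expr) <- samples
    gm <- matrix(c(g, g2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("snpA", "snpB"), samples))
    list(
      genotypes = genotype_matrix(gm, positions = tibble::tibble(
        id = c("snpA", "snpB"), chrom = c("chr1", "chr2"),
        pos = c(10000000L, 50000000L)
      )),
      expression = expression_matrix(expr, positions = tibble::tibble(
        id = rownames(expr), chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr3"),
        pos = c(12000000L, 40000000L, 49000000L, 90000000L, 1000000L, 2000000L)
      ))
    )
  })
}

make_eqtl_table <- function(n_cis = 5, n_trans = 5, cis_mean = 1, trans_mean = 0.3,
                            sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      snp_id = sprintf("snp%02d", seq_len(n_cis + n_trans)),
      gene_id = sprintf("gene%02d", seq_len(n_cis + n_trans)),
      relevance_bits = abs(c(rnorm(n_cis, cis_mean, sd), rnorm(n_trans, trans_mean, sd))),
      mrmr_score = c(rnorm(n_cis, cis_mean, sd), rnorm(n_trans, trans_mean, sd)),
      loocv_accuracy = 0.95,
      cis_class = rep(c("cis", "trans"), c(n_cis, n_trans)),
      distance_bp = NA_integer_
    )
  })
}
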