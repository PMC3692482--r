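small_spec <- function(...) {
  simulation_spec(
    n_samples = 100, n_snps = 10, n_genes = 40, n_chromosomes = 3,
    cis_fraction = 0.2, trans_fraction = 0.2, prop_active_snps = 0.3,
    additive_range = c(2, 3), network_degree = 4, ...
  )
}

test_that("the same seed reproduces a bit-identical dataset", {
  s1 <- simulate_eqtl_dataset(small_spec(seed = 123))
  s2 <- simulate_eqtl_dataset(small_spec(seed = 123))
  expect_identical(s1$genotypes$values, s2$genotypes$values)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  s3 <- simulate_eqtl_dataset(small_spec(seed = 124))
  expect_false(identical(s1$expression$values, s3$expression$values))
})

test_that("genotype frequencies follow the Mendelian 1:2:1 expectation", {
  withr::with_seed(103, {
    spec <- simulation_spec(n_samples = 5000, n_snps = 6, n_genes = 1,
                            n_chromosomes = 2, cis_fraction = 0,
                            trans_fraction = 0, network_degree = 0)
    g <- simulate_genotypes(spec)
    for (m in seq_len(6)) {
      counts <- tabulate(g$values[m, ], nbins = 3)
      p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
      expect_gt(p, 0.01)
    }
  })
})

test_that("recombination controls adjacent-marker dependence", {
  withr::with_seed(107, {
    # free recombination: adjacent markers uncorrelated
    spec_free <- simulation_spec(n_samples = 5000, n_snps = 4, n_genes = 1,
                                 n_chromosomes = 1, recomb_fraction = 0.5,
                                 cis_fraction = 0, trans_fraction = 0,
                                 network_degree = 0)
    g <- simulate_genotypes(spec_free)$values
    expect_lt(abs(cor(g[1, ], g[2, ])), 0.05)
    # tight linkage: genotype concordance approaches (1 - 2r(1-r))^2 + ...
    spec_tight <- simulation_spec(n_samples = 1000, n_snps = 4, n_genes = 1,
                                  n_chromosomes = 1, recomb_fraction = 0.01,
                                  cis_fraction = 0, trans_fraction = 0,
                                  network_degree = 0)
    g <- simulate_genotypes(spec_tight)$values
    concordance <- mean(g[1, ] == g[2, ])
    expect_gt(concordance, 0.95)
    # analytic per-gamete switch probability 2r(1-r) = 0.0198: genotype
    # concordance >= 1 - 2 * 0.0198
    expect_gt(concordance, 1 - 2 * 2 * 0.01 * 0.99)
  })
})

test_that("null effects yield expression independent of genotype", {
  withr::with_seed(109, {
    spec <- simulation_spec(n_samples = 250, n_snps = 5, n_genes = 30,
                            n_chromosomes = 2, cis_fraction = 0,
                            trans_fraction = 0, network_degree = 0)
    g <- simulate_genotypes(spec)
    ex <- simulate_expression(g, spec)
    expect_identical(nrow(ex$truth), 0L)
    scores <- maxrel_scores(g, ex$expression)
    expect_lt(mean(scores$score), 0.05)
  })
})

test_that("a strong planted additive pair has maximal MI among all genes", {
  withr::with_seed(113, {
    hits <- replicate(30, {
      spec <- simulation_spec(n_samples = 250, n_snps = 4, n_genes = 25,
                              n_chromosomes = 2, cis_fraction = 0.04,
                              trans_fraction = 0, prop_active_snps = 0.25,
                              additive_range = c(3, 3), network_degree = 0)
      g <- simulate_genotypes(spec)
      ex <- simulate_expression(g, spec)
      stopifnot(nrow(ex$truth) == 1)
      scores <- maxrel_scores(g, ex$expression)
      snp_scores <- scores[scores$snp_id == ex$truth$snp_id, ]
      snp_scores$gene_id[which.max(snp_scores$score)] == ex$truth$gene_id
    })
    expect_gte(mean(hits), 0.95)
  })
})

test_that("dominance-only effects are seen by MI but not by linear correlation", {
  withr::with_seed(127, {
    spec <- simulation_spec(n_samples = 250, n_snps = 2, n_genes = 10,
                            n_chromosomes = 2, cis_fraction = 0.1,
                            trans_fraction = 0, prop_active_snps = 0.5,
                            additive_range = c(0, 0), dominance_range = c(3, 3),
                            network_degree = 0)
    g <- simulate_genotypes(spec)
    ex <- simulate_expression(g, spec)
    pair <- ex$truth[1, ]
    geno <- g$values[pair$snp_id, ]
    expr <- ex$expression$values[pair$gene_id, ]
    expect_lt(abs(cor(geno, expr)), 0.2)
    mi <- mutual_information(discretize_gene(expr), geno)
    other_mi <- sapply(setdiff(rownames(ex$expression$values), pair$gene_id),
                       function(gid) {
                         mutual_information(discretize_gene(ex$expression$values[gid, ]), geno)
                       })
    expect_gt(mi, max(other_mi))
  })
})

test_that("planted cis pairs satisfy the cis annotation; trans pairs do not", {
  sim <- simulate_eqtl_dataset(small_spec(seed = 131))
  mpos <- sim$genotypes$positions
  gpos <- sim$expression$positions
  cls <- classify_cis_trans(
    mpos$chrom[match(sim$truth$snp_id, mpos$id)],
    mpos$pos[match(sim$truth$snp_id, mpos$id)],
    gpos$chrom[match(sim$truth$gene_id, gpos$id)],
    gpos$pos[match(sim$truth$gene_id, gpos$id)]
  )
  expect_identical(cls, sim$truth$class)
})

test_that("raising the noise level monotonically weakens planted MI signal", {
  mean_mi <- sapply(c(0.5, 1.5, 4), function(sd) {
    sim <- simulate_eqtl_dataset(simulation_spec(
      n_samples = 200, n_snps = 6, n_genes = 24, n_chromosomes = 2,
      cis_fraction = 0.25, trans_fraction = 0, prop_active_snps = 0.5,
      additive_range = c(2, 2), network_degree = 0, noise_sd = sd, seed = 137
    ))
    scores <- maxrel_scores(sim$genotypes, sim$expression)
    key <- paste(scores$snp_id, scores$gene_id)
    planted <- paste(sim$truth$snp_id, sim$truth$gene_id)
    mean(scores$score[key %in% planted])
  })
  expect_true(all(diff(mean_mi) < 0))
})

test_that("spec validation rejects impossible settings", {
  expect_error(simulation_spec(n_snps = 0), "n_snps")
  expect_error(simulation_spec(noise_sd = 0), "noise_sd")
  expect_error(simulation_spec(recomb_fraction = 0.7), "recomb_fraction")
  expect_error(simulation_spec(network_degree = 1000, n_genes = 100), "network_degree")
  expect_error(simulation_spec(cis_fraction = 0.8, trans_fraction = 0.5), "exceed")
  expect_error(simulation_spec(trans_fraction = 0.2, n_chromosomes = 1), "chromosomes")
})
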