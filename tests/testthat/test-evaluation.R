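pairs_universe <- function(n_snps, n_genes) {
  tidyr::expand_grid(snp_id = sprintf("s%03d", seq_len(n_snps)),
                     gene_id = sprintf("g%03d", seq_len(n_genes)))
}

test_that("perfect ranking yields a curve reaching precision 1 at recall 1", {
  uni <- pairs_universe(4, 5)
  truth <- uni[1:6, ]
  scores <- dplyr::mutate(uni, score = c(rep(2, 6), rep(1, 14)) + seq_len(20) * 1e-6)
  pr <- precision_recall(scores, truth, uni)
  expect_equal(aupr(pr), 1)
  expect_equal(max(pr$points$recall), 1)
  expect_equal(pr$points$precision[which(pr$points$recall == 1)[1]], 1)
})

test_that("a single positive ranked last scores AUPR = 1/N", {
  uni <- pairs_universe(2, 10)
  scores <- dplyr::mutate(uni, score = rev(seq_len(20)))
  truth <- uni[20, ]
  pr <- precision_recall(scores, truth, uni)
  expect_equal(aupr(pr), 1 / 20)
})

test_that("hand-enumerated 6-pair ranking matches, with tie-aware grouping", {
  uni <- pairs_universe(1, 6)
  score <- c(5, 4, 4, 3, 2, 2)
  pos <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  scores <- dplyr::mutate(uni, score = score)
  truth <- uni[pos, ]
  pr <- precision_recall(scores, truth, uni)
  manual <- oracle_pr_points(score, pos)
  expect_equal(pr$points$recall, unname(manual[, "recall"]))
  expect_equal(pr$points$precision, unname(manual[, "precision"]))
  # within-tie order cannot matter: permute rows inside the tie groups
  perm <- c(1, 3, 2, 4, 6, 5)
  pr2 <- precision_recall(scores[perm, ], truth, uni)
  expect_equal(pr2$points, pr$points)
})

test_that("random rankings concentrate near the positive fraction", {
  withr::with_seed(139, {
    uni <- pairs_universe(40, 50)
    truth <- uni[sample(2000, 200), ]
    auprs <- replicate(100, {
      aupr(precision_recall(dplyr::mutate(uni, score = rnorm(2000)), truth, uni))
    })
    expect_lt(abs(mean(auprs) - 0.1), 0.02)
  })
})

test_that("AUPR is invariant under strictly monotone score transforms", {
  withr::with_seed(149, {
    uni <- pairs_universe(10, 10)
    truth <- uni[sample(100, 12), ]
    scores <- dplyr::mutate(uni, score = round(rnorm(100), 1))  # with ties
    a1 <- aupr(precision_recall(scores, truth, uni))
    a2 <- aupr(precision_recall(dplyr::mutate(scores, score = exp(score)), truth, uni))
    a3 <- aupr(precision_recall(dplyr::mutate(scores, score = 5 * score - 2), truth, uni))
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_equal(a1, a3, tolerance = 1e-12)
  })
})

test_that("unscored universe pairs rank below every scored pair", {
  uni <- pairs_universe(2, 4)
  truth <- uni[1, ]
  scored <- dplyr::mutate(uni[1:5, ], score = c(0.1, 5, 4, 3, 2))
  pr <- precision_recall(scored, truth, uni)
  # the positive is the lowest-scored *scored* pair, but still above the
  # three unscored ones
  expect_equal(aupr(pr), 1 / 5)
})

test_that("precision_recall validates its inputs", {
  uni <- pairs_universe(2, 2)
  scores <- dplyr::mutate(uni, score = 1:4)
  expect_error(precision_recall(scores, uni[0, ], uni), "empty")
  out <- tibble::tibble(snp_id = "sX", gene_id = "gX")
  expect_error(precision_recall(scores, out, uni), "subset")
  expect_error(precision_recall(scores[c(1, 1), ], uni[1, ], uni), "duplicate")
})

test_that("relative AUPR rescales by the maximum", {
  expect_equal(raupr(c(0.2, 0.1)), c(1, 0.5))
  expect_equal(raupr(c(0.3, 0.3, 0.3)), c(1, 1, 1))
  expect_error(raupr(numeric(0)), "non-empty")
})

test_that("consensus counting matches set algebra on handcrafted tables", {
  t1 <- tibble::tibble(snp_id = c("a", "a", "b", "c"), gene_id = c("g1", "g2", "g1", "g3"))
  t2 <- tibble::tibble(snp_id = c("a", "b"), gene_id = c("g1", "g1"))
  t3 <- tibble::tibble(snp_id = c("a", "c"), gene_id = c("g1", "g3"))
  res <- consensus_counts(list(t1, t2, t3), reference_index = 1, min_confirmations = 2)
  expect_identical(res$n_confirmed, 1L)  # only (a, g1) is in both others
  expect_equal(res$fraction, 1 / 4)
  res1 <- consensus_counts(list(t1, t2, t3), reference_index = 1, min_confirmations = 1)
  expect_identical(res1$n_confirmed, 3L)  # (a,g1), (b,g1), (c,g3)
  # identical tables: full consensus; disjoint tables: none
  expect_equal(consensus_counts(list(t1, t1), min_confirmations = 1)$fraction, 1)
  t4 <- tibble::tibble(snp_id = "z", gene_id = "g9")
  expect_equal(consensus_counts(list(t1, t4), min_confirmations = 1)$fraction, 0)
})

test_that("MI scoring beats the linear baseline on dominance-only effects", {
  withr::with_seed(151, {
    wins <- replicate(8, {
      spec <- simulation_spec(
        n_samples = 150, n_snps = 12, n_genes = 40, n_chromosomes = 3,
        cis_fraction = 0.15, trans_fraction = 0.15, prop_active_snps = 0.25,
        additive_range = c(0, 0), dominance_range = c(2.5, 3.5),
        network_degree = 0
      )
      g <- simulate_genotypes(spec)
      ex <- simulate_expression(g, spec)
      uni <- tidyr::expand_grid(snp_id = rownames(g$values),
                                gene_id = rownames(ex$expression$values))
      truth <- ex$truth[c("snp_id", "gene_id")]
      a_mi <- aupr(precision_recall(maxrel_scores(g, ex$expression), truth, uni))
      a_r <- aupr(precision_recall(pearson_scores(g, ex$expression), truth, uni))
      a_mi > a_r
    })
    expect_gte(mean(wins), 7 / 8)
  })
})

test_that("MI and the linear baseline are comparable on purely additive effects", {
  withr::with_seed(157, {
    diffs <- replicate(8, {
      spec <- simulation_spec(
        n_samples = 150, n_snps = 12, n_genes = 40, n_chromosomes = 3,
        cis_fraction = 0.15, trans_fraction = 0.15, prop_active_snps = 0.25,
        additive_range = c(2.5, 3.5), dominance_range = c(0, 0),
        trans_effect_scale = 1, network_degree = 0
      )
      g <- simulate_genotypes(spec)
      ex <- simulate_expression(g, spec)
      uni <- tidyr::expand_grid(snp_id = rownames(g$values),
                                gene_id = rownames(ex$expression$values))
      truth <- ex$truth[c("snp_id", "gene_id")]
      a_mi <- aupr(precision_recall(maxrel_scores(g, ex$expression), truth, uni))
      a_r <- aupr(precision_recall(pearson_scores(g, ex$expression), truth, uni))
      a_mi - a_r
    })
    expect_lt(abs(mean(diffs)), 0.06)
  })
})

test_that("network-propagated indirect associations are filtered by mRMR", {
  withr::with_seed(163, {
    spec <- simulation_spec(
      n_samples = 200, n_snps = 4, n_genes = 30, n_chromosomes = 2,
      cis_fraction = 0.1, trans_fraction = 0.1, prop_active_snps = 0.5,
      additive_range = c(3, 3), network_degree = 6, network_weight = 0.3
    )
    g <- simulate_genotypes(spec)
    ex <- simulate_expression(g, spec)
    scan <- map_eqtls(g, ex$expression, eqtl_config(k_rank = 10, accuracy_cutoff = 0))
    # within each emitting marker's mRMR list, planted direct genes carry
    # higher mean mrmr scores than indirect/noise genes
    truth_key <- paste(ex$truth$snp_id, ex$truth$gene_id)
    for (snp in unique(ex$truth$snp_id)) {
      mr <- scan$rankings[[snp]]$mrmr
      planted <- paste(snp, mr$gene_id) %in% truth_key
      if (any(planted) && any(!planted)) {
        expect_gt(mean(mr$mrmr_score[planted]), mean(mr$mrmr_score[!planted]))
      }
    }
  })
})
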