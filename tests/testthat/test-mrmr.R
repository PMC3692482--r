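test_that("relevance and redundancy reduce to (mean) mutual information", {
  withr::with_seed(43, {
    gene <- random_states(40)
    geno <- sample(1:3, 40, replace = TRUE)
    expect_equal(relevance(gene, geno), oracle_mi(gene, geno), tolerance = 1e-12)
    # identical to the class label: relevance = H(genotype)
    expect_equal(relevance(geno, geno), entropy_bits(geno))
    # orthogonal pattern: zero relevance
    expect_equal(relevance(rep(c(0L, 1L), 20), rep(c(1L, 1L, 2L, 2L), 10)), 0)
    # redundancy of a gene against its own copy is its entropy
    expect_equal(redundancy(gene, list(gene)), entropy_bits(gene))
    sel <- list(random_states(40), random_states(40), random_states(40))
    expect_equal(redundancy(gene, sel),
                 mean(sapply(sel, function(s) oracle_mi(gene, s))),
                 tolerance = 1e-12)
    expect_error(redundancy(gene, list()), "non-empty")
  })
})

test_that("mRMR demotes a duplicated top gene below a fresh moderate gene", {
  geno <- rep(c(1L, 2L, 3L), each = 10)
  a <- geno
  a[c(1, 11, 21)] <- c(2L, 3L, 1L)   # strong but imperfect proxy of the genotype
  b <- a                             # exact duplicate of A
  c_ <- geno
  c_[seq(1, 29, by = 2)] <- rep(c(3L, 1L, 2L), 5)  # weaker, partly fresh signal
  states <- rbind(A = a, B = b, C = c_)
  colnames(states) <- sprintf("s%02d", 1:30)
  r <- mrmr_rank(states, geno, K = 3)
  # A wins round 1 (tie with its duplicate broken by input order); in round
  # 2 B pays full redundancy H(A) while C's smaller redundancy leaves it a
  # positive margin, so B drops to last
  expect_identical(r$mrmr$gene_id, c("A", "C", "B"))
  oracle <- oracle_greedy_mrmr(states, geno, 3)
  expect_identical(r$mrmr$gene_id, rownames(states)[oracle$order])
  expect_equal(r$mrmr$mrmr_score, oracle$scores, tolerance = 1e-10)
})

test_that("single gene, K = 1: score equals its relevance and lists agree", {
  withr::with_seed(53, {
    geno <- sample(1:3, 25, replace = TRUE)
    states <- rbind(only = random_states(25))
    r <- mrmr_rank(states, geno, K = 1)
    expect_identical(r$mrmr$gene_id, "only")
    expect_equal(r$mrmr$mrmr_score, r$mrmr$relevance_bits)
    expect_identical(r$maxrel$gene_id[1], r$mrmr$gene_id[1])
    expect_error(mrmr_rank(states, geno, K = 0), "positive")
  })
})

test_that("greedy selection matches the brute-force oracle on random instances", {
  withr::with_seed(59, {
    for (rep in 1:60) {
      G <- sample(3:8, 1)
      n <- sample(10:40, 1)
      states <- matrix(random_states(G * n), G, n,
                       dimnames = list(sprintf("g%02d", 1:G), NULL))
      geno <- sample(1:3, n, replace = TRUE)
      K <- sample(seq_len(G), 1)
      r <- mrmr_rank(states, geno, K = K)
      oracle <- oracle_greedy_mrmr(states, geno, K)
      expect_identical(r$mrmr$gene_id, rownames(states)[oracle$order])
      expect_equal(r$mrmr$mrmr_score, oracle$scores, tolerance = 1e-10)
      # maxrel is sorted non-increasing and covers all genes
      expect_identical(sort(r$maxrel$gene_id), sort(rownames(states)))
      expect_true(all(diff(r$maxrel$relevance_bits) <= 1e-12))
      # first selected gene maximises relevance
      expect_equal(r$mrmr$relevance_bits[1], max(oracle$relevance))
    }
  })
})

test_that("dropping a never-selected gene leaves the selection unchanged", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      n <- 30
      states <- matrix(random_states(6 * n), 6, n,
                       dimnames = list(paste0("g", 1:6), NULL))
      geno <- sample(1:3, n, replace = TRUE)
      r <- mrmr_rank(states, geno, K = 3)
      unselected <- setdiff(rownames(states), r$mrmr$gene_id)
      if (length(unselected) > 0) {
        keep <- setdiff(rownames(states), unselected[1])
        r2 <- mrmr_rank(states[keep, , drop = FALSE], geno, K = 3)
        expect_identical(r2$mrmr$gene_id, r$mrmr$gene_id)
      }
    }
  })
})

test_that("empty covariate list matches the plain path bit-for-bit", {
  withr::with_seed(67, {
    n <- 30
    states <- matrix(random_states(5 * n), 5, n,
                     dimnames = list(paste0("g", 1:5), NULL))
    geno <- sample(1:3, n, replace = TRUE)
    plain <- mrmr_rank(states, geno, K = 5)
    # conditioning on a constant covariate is the identity adjustment
    const <- mrmr_rank(states, geno, K = 5, covariates = list(rep(1L, n)))
    expect_identical(const$mrmr$gene_id, plain$mrmr$gene_id)
    expect_equal(const$mrmr$mrmr_score, plain$mrmr$mrmr_score, tolerance = 1e-12)
    # a real covariate changes relevance to the conditional MI
    z <- sample(0:1, n, replace = TRUE)
    adj <- mrmr_rank(states, geno, K = 5, covariates = list(z))
    expect_equal(
      adj$maxrel$relevance_bits[match("g1", adj$maxrel$gene_id)],
      oracle_cmi(states["g1", ], geno, z),
      tolerance = 1e-10
    )
  })
})
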