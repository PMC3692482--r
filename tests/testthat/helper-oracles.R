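# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals: entropies
# and mutual information are computed by direct summation over contingency
# tables built with table(), greedy selection and LOOCV by plain loops.

oracle_entropy <- function(...) {
  tab <- table(...)
  p <- as.vector(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj)
  py <- colSums(pj)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (pj[i, j] > 0) {
        total <- total + pj[i, j] * log2(pj[i, j] / (px[i] * py[j]))
      }
    }
  }
  unname(total)
}

# CMI as the z-stratified mixture of per-stratum MI values.
oracle_cmi <- function(x, y, z) {
  total <- 0
  for (zv in unique(z)) {
    idx <- z == zv
    total <- total + mean(idx) * oracle_mi(x[idx], y[idx])
  }
  unname(total)
}

# Brute-force greedy mRMR: recompute relevance and full redundancy sums at
# every round, difference scheme, ties by input order. Ties are called at
# 1e-9: criterion values that coincide in real arithmetic can differ by a
# few ulp between summation orders, and the tie rule must not depend on
# that.
oracle_greedy_mrmr <- function(states, genotype, K) {
  G <- nrow(states)
  d <- sapply(seq_len(G), function(i) oracle_mi(states[i, ], genotype))
  selected <- integer(0)
  scores <- numeric(0)
  for (round in seq_len(K)) {
    best <- NA_integer_
    best_val <- -Inf
    for (i in setdiff(seq_len(G), selected)) {
      if (length(selected) == 0) {
        val <- d[i]
      } else {
        red <- mean(sapply(selected, function(s) oracle_mi(states[i, ], states[s, ])))
        val <- d[i] - red
      }
      if (val > best_val + 1e-9) {  # ties keep the earlier index
        best_val <- val
        best <- i
      }
    }
    selected <- c(selected, best)
    scores <- c(scores, best_val)
  }
  list(order = selected, scores = scores, relevance = d)
}

oracle_cosine <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Plain-loop LOOCV with 1-nearest-neighbour under cosine distance.
oracle_loocv <- function(features, labels) {
  n <- nrow(features)
  pred <- vector(mode = mode(labels), length = n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    dist <- sapply(train, function(j) oracle_cosine(features[j, ], features[i, ]))
    pred[i] <- labels[train[which.min(dist)]]
  }
  mean(pred == labels)
}

# Exact hypergeometric upper tail by enumeration of the pmf.
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Hand enumeration of tie-aware PR points from a scored universe.
oracle_pr_points <- function(score, pos) {
  ord <- order(-score)
  score <- score[ord]
  pos <- pos[ord]
  thresholds <- unique(score)
  t(sapply(thresholds, function(th) {
    sel <- score >= th
    c(recall = sum(pos & sel) / sum(pos), precision = sum(pos & sel) / sum(sel))
  }))
}
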