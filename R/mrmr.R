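#' Relevance of a gene to a marker genotype, in bits
#'
#' Mutual information between the discretized expression states of a gene
#' and the genotype class label; with covariates, the conditional mutual
#' information given the (jointly coded) covariates.
#'
#' @param gene Discrete expression states of one gene.
#' @param genotype Genotype states (class label), same length.
#' @param covariates Optional discrete vector or list of discrete vectors to
#'   condition on.
#' @return Relevance in bits.
#' @export
relevance <- function(gene, genotype, covariates = NULL) {
  if (is.null(covariates)) {
    mutual_information(gene, genotype)
  } else {
    conditional_mutual_information(gene, genotype, covariates)
  }
}

#' Redundancy of a gene against an already-selected gene set, in bits
#'
#' Mean mutual information between `gene` and each member of `selected`.
#'
#' @param gene Discrete expression states of one gene.
#' @param selected Non-empty list of discrete vectors (or a matrix with one
#'   selected gene per row).
#' @return Redundancy in bits.
#' @export
redundancy <- function(gene, selected) {
  if (is.matrix(selected)) {
    selected <- lapply(seq_len(nrow(selected)), function(i) selected[i, ])
  }
  if (!is.list(selected) || length(selected) == 0L) {
    abort("`selected` must be a non-empty list of discrete vectors.")
  }
  mean(vapply(selected, function(s) mutual_information(gene, s), numeric(1)))
}

# First index attaining the maximum up to a small numerical tolerance:
# criterion values that tie in real arithmetic can differ by a few ulp
# depending on summation order, and the input-order tie rule must not
# depend on that.
.argmax_tol <- function(v, tol = 1e-9) {
  which(v >= max(v) - tol)[1L]
}

#' Rank genes for one marker by MaxRel and by mRMR
#'
#' Computes the maximum-relevance (MaxRel) ordering of all genes by mutual
#' information with the genotype, and the greedy
#' maximum-relevance-minimum-redundancy (mRMR) selection of the top `K`
#' genes. Round 1 picks the gene with maximal relevance `D`; round `j > 1`
#' picks the gene maximising `D - R` (difference scheme, default) or
#' `D / R` (quotient scheme), where `R` is the mean mutual information with
#' the `j - 1` genes already selected. Ties (up to a small numerical
#' tolerance) are broken by input gene order, so the selection is
#' deterministic. With covariates, relevance is replaced
#' by conditional mutual information given the covariates.
#'
#' @param states Integer matrix of discretized expression, genes in rows
#'   (rownames = gene ids), samples in columns.
#' @param genotype Genotype states, one per sample.
#' @param K Number of genes to carry into the mRMR list (1 <= K <= n genes).
#'   Default 50 (capped at the number of genes).
#' @param covariates Optional discrete vector or list of discrete vectors.
#' @param scheme `"mid"` (difference, default) or `"miq"` (quotient).
#' @param snp_id Optional marker id recorded on the result.
#' @return An object of class `feature_ranking` with fields `snp_id`,
#'   `maxrel` (tibble `gene_id`, `relevance_bits` over ALL genes, sorted
#'   non-increasing), `mrmr` (tibble `gene_id`, `mrmr_score`,
#'   `relevance_bits` in selection order), and `K`.
#' @export
mrmr_rank <- function(states, genotype, K = 50L, covariates = NULL,
                      scheme = c("mid", "miq"), snp_id = NA_character_) {
  scheme <- arg_match(scheme)
  if (!is.matrix(states) || is.null(rownames(states))) {
    abort("`states` must be a matrix with gene ids as rownames.")
  }
  n_genes <- nrow(states)
  if (n_genes == 0L) abort("at least one gene is required.")
  if (length(genotype) != ncol(states)) {
    abort("`genotype` must have one entry per sample (column of `states`).")
  }
  K <- as.integer(K)
  if (is.na(K) || K <= 0L) abort("`K` must be a positive integer.")
  K <- min(K, n_genes)

  state_levels <- sort(unique(as.vector(states)))
  geno_levels <- sort(unique(genotype))
  nx <- length(state_levels)
  ng <- length(geno_levels)
  coded <- matrix(match(states, state_levels), nrow = n_genes)
  gcode <- match(genotype, geno_levels)

  if (is.null(covariates)) {
    d <- .mi_many(coded, gcode, nx, ng)
  } else {
    d <- vapply(seq_len(n_genes),
                function(i) conditional_mutual_information(states[i, ], genotype, covariates),
                numeric(1))
  }

  ord <- order(-d, seq_len(n_genes))  # stable: ties by input gene order
  maxrel <- tibble(gene_id = rownames(states)[ord], relevance_bits = d[ord])

  selected <- integer(K)
  scores <- numeric(K)
  available <- rep(TRUE, n_genes)
  redsum <- numeric(n_genes)
  first <- .argmax_tol(d)  # ties -> first index
  selected[1L] <- first
  scores[1L] <- d[first]
  available[first] <- FALSE
  if (K > 1L) {
    for (j in 2L:K) {
      last <- selected[j - 1L]
      redsum <- redsum + .mi_many(coded, coded[last, ], nx, nx)
      r <- redsum / (j - 1L)
      val <- switch(scheme,
        mid = d - r,
        miq = d / pmax(r, .Machine$double.eps)
      )
      val[!available] <- -Inf
      pick <- .argmax_tol(val)
      selected[j] <- pick
      scores[j] <- val[pick]
      available[pick] <- FALSE
    }
  }
  structure(
    list(
      snp_id = snp_id,
      maxrel = maxrel,
      mrmr = tibble(
        gene_id = rownames(states)[selected],
        mrmr_score = scores,
        relevance_bits = d[selected]
      ),
      K = K,
      scheme = scheme
    ),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf(
    "<feature_ranking>%s %d genes ranked, mRMR list of %d (%s scheme)\n",
    if (is.na(x$snp_id)) "" else sprintf(" %s:", x$snp_id),
    nrow(x$maxrel), x$K, x$scheme
  ))
  print(utils::head(x$mrmr, 5))
  invisible(x)
}

#' @rdname mrmr_rank
#' @param x A `feature_ranking`.
#' @param list Which list to return: `"mrmr"` (selection order, default) or
#'   `"maxrel"` (all genes by relevance).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.feature_ranking <- function(x, list = c("mrmr", "maxrel"), ...) {
  list <- arg_match(list)
  out <- x[[list]]
  mutate(out, rank = seq_len(nrow(out)), snp_id = x$snp_id,
         .before = 1L)
}
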