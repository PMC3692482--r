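.pair_key <- function(snp_id, gene_id) paste(snp_id, gene_id, sep = "\r")

#' Precision-recall curve for scored SNP-gene associations
#'
#' Pairs are sorted by descending score (stable in input order within
#' ties) and precision/recall are computed at each distinct score
#' threshold, so the curve does not depend on the within-tie order. The
#' candidate universe must be passed explicitly; universe pairs without a
#' score are treated as scored below every scored pair.
#'
#' @param scores Tibble/data frame with columns `snp_id`, `gene_id`,
#'   `score` (one row per scored pair; pairs must be unique).
#' @param truth Tibble with columns `snp_id`, `gene_id` listing the true
#'   (planted) pairs; must be a subset of `universe` and non-empty.
#' @param universe Tibble with columns `snp_id`, `gene_id`: all candidate
#'   pairs (the recall denominator's complement set).
#' @return An object of class `pr_curve`: `points` (tibble `threshold`,
#'   `recall`, `precision`, ordered by descending threshold),
#'   `n_positives`, `n_universe`.
#' @export
precision_recall <- function(scores, truth, universe) {
  scores <- as_tibble(scores)
  truth <- as_tibble(truth)
  universe <- as_tibble(universe)
  if (!all(c("snp_id", "gene_id", "score") %in% names(scores))) {
    abort("`scores` needs columns snp_id, gene_id, score.")
  }
  if (!all(c("snp_id", "gene_id") %in% names(truth)) ||
      !all(c("snp_id", "gene_id") %in% names(universe))) {
    abort("`truth` and `universe` need columns snp_id, gene_id.")
  }
  if (nrow(truth) == 0L) abort("`truth` is empty; recall is undefined.")
  ukey <- .pair_key(universe$snp_id, universe$gene_id)
  if (anyDuplicated(ukey)) abort("`universe` contains duplicate pairs.")
  tkey <- unique(.pair_key(truth$snp_id, truth$gene_id))
  if (!all(tkey %in% ukey)) abort("`truth` must be a subset of `universe`.")
  skey <- .pair_key(scores$snp_id, scores$gene_id)
  if (anyDuplicated(skey)) abort("`scores` contains duplicate pairs.")
  s <- scores$score[match(ukey, skey)]
  s[is.na(s)] <- -Inf
  pos <- ukey %in% tkey
  ord <- order(-s)  # stable
  s <- s[ord]
  pos <- pos[ord]
  cum_tp <- cumsum(pos)
  k <- seq_along(s)
  last_of_group <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cum_tp[last_of_group]
  at <- k[last_of_group]
  n_pos <- sum(pos)
  points <- tibble(
    threshold = s[last_of_group],
    recall = tp / n_pos,
    precision = tp / at
  )
  structure(
    list(points = points, n_positives = n_pos, n_universe = length(ukey)),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d threshold(s), %d positives of %d candidate pairs, AUPR = %.4f\n",
              nrow(x$points), x$n_positives, x$n_universe, aupr(x)))
  invisible(x)
}

#' @rdname precision_recall
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pr_curve <- function(x, ...) x$points

#' @rdname precision_recall
#' @exportS3Method generics::glance
glance.pr_curve <- function(x, ...) {
  tibble(aupr = aupr(x), n_positives = x$n_positives, n_universe = x$n_universe)
}

#' Plot a precision-recall curve
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Area under a precision-recall curve (average-precision form)
#'
#' Step integration `sum_i (R_i - R_{i-1}) * P_i` over the curve's
#' distinct-threshold points (not the trapezoid rule).
#'
#' @param curve A `pr_curve` from [precision_recall()].
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  r <- curve$points$recall
  p <- curve$points$precision
  sum(diff(c(0, r)) * p)
}

#' Relative AUPR: rescale a set of AUPRs by their maximum
#'
#' @param auprs Non-empty numeric vector of AUPR values (max must be > 0).
#' @return Numeric vector of the same length; the maximum maps to 1.
#' @examples
#' raupr(c(0.2, 0.1)) # 1.0 0.5
#' @export
raupr <- function(auprs) {
  if (!is.numeric(auprs) || length(auprs) == 0L) {
    abort("`auprs` must be a non-empty numeric vector.")
  }
  m <- max(auprs)
  if (!is.finite(m) || m <= 0) abort("the maximum AUPR must be positive.")
  auprs / m
}

#' Count consensus of a reference eQTL table with other tables
#'
#' A reference pair is confirmed when the same `(snp_id, gene_id)` pair
#' appears in at least `min_confirmations` of the other tables.
#'
#' @param tables List of eQTL tibbles (columns `snp_id`, `gene_id` at
#'   least).
#' @param reference_index Which table is the reference. Default 1.
#' @param min_confirmations Minimum number of other tables containing a
#'   pair for it to count as confirmed. Default 1.
#' @return A list with `fraction` (confirmed / reference pairs) and
#'   `n_confirmed`.
#' @export
consensus_counts <- function(tables, reference_index = 1L, min_confirmations = 1L) {
  if (!is.list(tables) || length(tables) < 2L) {
    abort("`tables` must be a list of at least two eQTL tables.")
  }
  if (reference_index < 1L || reference_index > length(tables)) {
    abort("`reference_index` out of range.")
  }
  keys <- lapply(tables, function(tb) {
    tb <- as_tibble(tb)
    unique(.pair_key(tb$snp_id, tb$gene_id))
  })
  ref <- keys[[reference_index]]
  if (length(ref) == 0L) abort("the reference table has no pairs.")
  others <- keys[-reference_index]
  support <- rowSums(vapply(others, function(k) ref %in% k,
                            logical(length(ref))))
  n_confirmed <- sum(support >= min_confirmations)
  list(fraction = n_confirmed / length(ref), n_confirmed = n_confirmed)
}

#' MaxRel mutual-information scores for every SNP-gene pair
#'
#' Discretizes expression and computes the mutual information between each
#' marker genotype and each gene, the score used for precision-recall
#' evaluation of the method. Samples with missing genotype are dropped per
#' marker.
#'
#' @param genotypes A [genotype_matrix()].
#' @param expression An [expression_matrix()].
#' @param t Discretization threshold in standard deviations. Default 1.
#' @return A tibble `snp_id`, `gene_id`, `score` (bits) over all pairs.
#' @export
maxrel_scores <- function(genotypes, expression, t = 1) {
  paired <- pair_samples(genotypes, expression)
  gv <- paired$genotypes$values
  states <- discretize_expression(paired$expression$values, t = t)
  state_levels <- sort(unique(as.vector(states)))
  coded <- matrix(match(states, state_levels), nrow = nrow(states))
  nx <- length(state_levels)
  purrr::map_dfr(seq_len(nrow(gv)), function(m) {
    g <- gv[m, ]
    use <- !is.na(g)
    gl <- sort(unique(g[use]))
    gc <- match(g[use], gl)
    mi <- vapply(seq_len(nrow(coded)),
                 function(i) .mi_coded(coded[i, use], gc, nx, length(gl)),
                 numeric(1))
    tibble(snp_id = rownames(gv)[m], gene_id = rownames(states), score = mi)
  })
}

#' Per-pair absolute Pearson correlation scores
#'
#' The linear-association baseline: `|cor(genotype dose, expression)|` for
#' every SNP-gene pair, with pairwise-complete handling of missing
#' genotypes.
#'
#' @inheritParams maxrel_scores
#' @return A tibble `snp_id`, `gene_id`, `score`.
#' @export
pearson_scores <- function(genotypes, expression) {
  paired <- pair_samples(genotypes, expression)
  gv <- paired$genotypes$values
  ev <- paired$expression$values
  cc <- suppressWarnings(stats::cor(t(ev), t(gv), use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0  # constant marker or gene: no linear signal
  tidyr::expand_grid(snp_id = rownames(gv), gene_id = rownames(ev)) %>%
    mutate(score = abs(cc[cbind(.data$gene_id, .data$snp_id)]))
}
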