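#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` are partners, the probability of observing
#' at least `k` partners. Computed through the distribution function's
#' stable tail, so small p-values do not underflow to garbage.
#'
#' @param N Universe size.
#' @param K Number of partner genes in the universe.
#' @param n Size of the drawn (affected) gene set.
#' @param k Observed overlap.
#' @return The upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(10, 3, 4, 2) # 70/210
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0)) {
    abort("N, K, n, k must be non-negative integers.")
  }
  if (K > N || n > N || k > min(n, K)) {
    abort("inconsistent counts: need k <= min(n, K) and n, K <= N.")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of affected-gene sets in a partner list
#'
#' For each marker in an eQTL table, tests whether its affected genes
#' overlap a partner gene list more than expected by chance, against a
#' fixed gene universe. One upper-tail hypergeometric test per marker;
#' following the original analysis, no multiple-testing correction is
#' applied by default (raw `p < alpha` is flagged), but Benjamini-Hochberg
#' or Bonferroni adjustment is available.
#'
#' @param table An eQTL tibble (or `eqtl_scan`) with columns `snp_id`,
#'   `gene_id`.
#' @param partners Character vector of partner gene ids.
#' @param universe Character vector of all gene ids eligible for selection
#'   (e.g. every gene on the platform entering the analysis).
#' @param alpha Significance threshold on the (possibly adjusted) p-value.
#'   Default 0.05.
#' @param adjust Multiple-testing adjustment: `"none"` (default), `"BH"`
#'   or `"bonferroni"` (passed to [stats::p.adjust()]).
#' @return A tibble with one row per marker: `snp_id`, `k` (overlap),
#'   `n` (affected genes in universe), `K` (partners in universe),
#'   `N` (universe size), `p_value`, `significant`.
#' @export
enrich_all <- function(table, partners, universe, alpha = 0.05,
                       adjust = c("none", "BH", "bonferroni")) {
  adjust <- arg_match(adjust)
  if (inherits(table, "eqtl_scan")) table <- table$table
  table <- as_tibble(table)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) abort("`universe` is empty.")
  partners <- intersect(unique(as.character(partners)), universe)
  N <- length(universe)
  K <- length(partners)
  per_snp <- table %>%
    group_by(.data$snp_id) %>%
    summarise(genes = list(intersect(unique(.data$gene_id), universe)),
              .groups = "drop")
  out <- tibble(
    snp_id = per_snp$snp_id,
    k = vapply(per_snp$genes, function(g) length(intersect(g, partners)), integer(1)),
    n = lengths(per_snp$genes),
    K = K, N = N
  )
  out$p_value <- purrr::map2_dbl(out$k, out$n,
                                 function(ki, ni) hypergeom_upper_tail(N, K, ni, ki))
  p_adj <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- p_adj < alpha
  arrange(out, .data$p_value, .data$snp_id)
}
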