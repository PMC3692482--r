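#' Pipeline configuration for eQTL mapping
#'
#' Collects the tunable parameters of the per-marker workflow. Defaults:
#' mRMR depth `k_rank = 50`, discretization threshold `discretize_t = 1`
#' standard deviation, difference-scheme mRMR, IFS on the mRMR list,
#' reporting cutoff `accuracy_cutoff = 0.90` on the overall jackknife
#' accuracy, and a 5 Mb cis window.
#'
#' @param k_rank Number of top mRMR genes carried into IFS (positive).
#' @param discretize_t Discretization threshold in standard deviations.
#' @param mrmr_scheme `"mid"` (difference) or `"miq"` (quotient).
#' @param ifs_list Which ranked list IFS consumes: `"mrmr"` or `"maxrel"`.
#' @param accuracy_cutoff Minimum overall LOOCV accuracy for a marker's
#'   optimal gene set to be reported, in `[0, 1]` (values above 1 are
#'   allowed and simply unattainable).
#' @param cis_window_bp Maximum SNP-to-gene-start distance (bp, inclusive)
#'   for the cis call.
#' @param covariates Optional discrete covariates: a matrix/data frame with
#'   one row per covariate and one column per sample (colnames = sample ids).
#' @param var_equal Use a pooled-variance t-test in [compare_cis_trans()]
#'   instead of Welch. Default `FALSE`.
#' @return An object of class `eqtl_config`.
#' @export
eqtl_config <- function(k_rank = 50L, discretize_t = 1, mrmr_scheme = c("mid", "miq"),
                        ifs_list = c("mrmr", "maxrel"), accuracy_cutoff = 0.90,
                        cis_window_bp = 5e6, covariates = NULL, var_equal = FALSE) {
  mrmr_scheme <- arg_match(mrmr_scheme)
  ifs_list <- arg_match(ifs_list)
  if (!is.numeric(k_rank) || length(k_rank) != 1L || k_rank < 1) {
    abort("`k_rank` must be a positive integer.")
  }
  if (!is.numeric(accuracy_cutoff) || length(accuracy_cutoff) != 1L ||
      accuracy_cutoff < 0) {
    abort("`accuracy_cutoff` must be a non-negative number.")
  }
  if (!is.numeric(cis_window_bp) || length(cis_window_bp) != 1L || cis_window_bp <= 0) {
    abort("`cis_window_bp` must be positive.")
  }
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  structure(
    list(
      k_rank = as.integer(k_rank), discretize_t = discretize_t,
      mrmr_scheme = mrmr_scheme, ifs_list = ifs_list,
      accuracy_cutoff = accuracy_cutoff, cis_window_bp = cis_window_bp,
      covariates = covariates, var_equal = isTRUE(var_equal)
    ),
    class = "eqtl_config"
  )
}

#' @export
print.eqtl_config <- function(x, ...) {
  cat("<eqtl_config>\n")
  cat(sprintf("  k_rank = %d, discretize_t = %g, scheme = %s, ifs_list = %s\n",
              x$k_rank, x$discretize_t, x$mrmr_scheme, x$ifs_list))
  cat(sprintf("  accuracy_cutoff = %g, cis_window_bp = %g, covariates = %s\n",
              x$accuracy_cutoff, x$cis_window_bp,
              if (is.null(x$covariates)) "none" else nrow(x$covariates)))
  invisible(x)
}

#' Classify SNP-gene pairs as cis, trans or ambiguous
#'
#' A pair is `ambiguous` if either position is missing, `cis` if both lie
#' on the same chromosome and the SNP-to-gene-start distance is at most
#' `window_bp` (inclusive), otherwise `trans`.
#'
#' @param snp_chrom,snp_pos Marker chromosome (character) and position (bp);
#'   `NA` for unannotated markers.
#' @param gene_chrom,gene_pos Gene chromosome and transcription start (bp);
#'   `NA` for unannotated genes.
#' @param window_bp Cis window in bp (inclusive). Default 5e6.
#' @return Character vector in `{"cis", "trans", "ambiguous"}`, vectorised
#'   over its inputs.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_pos,
                               window_bp = 5e6) {
  n <- max(length(snp_chrom), length(snp_pos), length(gene_chrom), length(gene_pos))
  snp_chrom <- rep_len(as.character(snp_chrom), n)
  gene_chrom <- rep_len(as.character(gene_chrom), n)
  snp_pos <- rep_len(as.numeric(snp_pos), n)
  gene_pos <- rep_len(as.numeric(gene_pos), n)
  out <- rep("trans", n)
  missing <- is.na(snp_chrom) | is.na(snp_pos) | is.na(gene_chrom) | is.na(gene_pos)
  same <- !missing & snp_chrom == gene_chrom & abs(snp_pos - gene_pos) <= window_bp
  out[same] <- "cis"
  out[missing] <- "ambiguous"
  out
}

.lookup_pos <- function(positions, ids) {
  if (is.null(positions)) {
    return(tibble(chrom = rep(NA_character_, length(ids)),
                  pos = rep(NA_real_, length(ids))))
  }
  i <- match(ids, positions$id)
  tibble(chrom = positions$chrom[i], pos = as.numeric(positions$pos[i]))
}

# Run the per-marker workflow: mRMR ranking, IFS, cutoff, record emission.
.map_one_marker <- function(m, geno_values, states, expr_t, config, verbose) {
  g <- geno_values[m, ]
  use <- !is.na(g)
  skip <- function(reason) {
    if (verbose) message(sprintf("[%s] skipped: %s", m, reason))
    list(snp_id = m, skipped = reason, records = NULL, ifs = NULL, ranking = NULL)
  }
  if (sum(use) < 2L) return(skip("fewer than 2 samples with genotype calls"))
  g <- g[use]
  if (length(unique(g)) < 2L) return(skip("single genotype class"))
  covs <- config$covariates
  if (!is.null(covs)) {
    covs <- lapply(seq_len(nrow(covs)), function(i) covs[i, use])
  }
  ranking <- mrmr_rank(states[, use, drop = FALSE], g, K = config$k_rank,
                       covariates = covs, scheme = config$mrmr_scheme,
                       snp_id = m)
  ifs <- run_ifs(ranking, expr_t[use, , drop = FALSE], g, use = config$ifs_list)
  if (verbose) {
    message(sprintf("[%s] n = %d, optimal_k = %d, accuracy = %.4f, %s",
                    m, sum(use), ifs$optimal_k, ifs$optimal_accuracy,
                    if (ifs$optimal_accuracy >= config$accuracy_cutoff) "emitted" else "below cutoff"))
  }
  records <- NULL
  if (ifs$optimal_accuracy >= config$accuracy_cutoff) {
    genes <- ifs$optimal_genes
    rel <- ranking$maxrel$relevance_bits[match(genes, ranking$maxrel$gene_id)]
    score <- ranking$mrmr$mrmr_score[match(genes, ranking$mrmr$gene_id)]
    records <- tibble(
      snp_id = m, gene_id = genes,
      relevance_bits = rel, mrmr_score = score,
      loocv_accuracy = ifs$optimal_accuracy
    )
  }
  list(snp_id = m, skipped = NA_character_, records = records,
       ifs = ifs, ranking = ranking)
}

#' Map eQTLs: the five-step per-marker workflow
#'
#' For each marker: (1) align genotype and expression on shared samples;
#' (2) treat the genotype as the class label and gene expression as
#' features; (3) rank genes by mRMR (and MaxRel); (4) optimise the affected
#' gene set by incremental feature selection under jackknife
#' nearest-neighbour accuracy; (5) emit one record per optimal gene for
#' markers whose optimal accuracy reaches the reporting cutoff, annotated
#' cis/trans/ambiguous by genomic distance.
#'
#' Markers with a single genotype class (or fewer than two genotyped
#' samples) are skipped with a logged reason. Samples with missing genotype
#' calls are dropped for that marker only. The result is deterministic
#' given the inputs and configuration, and independent of `threads`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param expression An [expression_matrix()].
#' @param config An [eqtl_config()].
#' @param threads Number of worker processes for the per-marker loop
#'   (markers are independent). Default 1.
#' @param verbose Log one line per marker via `message()`. Default `FALSE`.
#' @return An object of class `eqtl_scan`: `table` (tibble with columns
#'   `snp_id`, `gene_id`, `relevance_bits`, `mrmr_score`, `loocv_accuracy`,
#'   `cis_class`, `distance_bp`), `ifs` and `rankings` (named lists per
#'   analysed marker), `skipped` (tibble `snp_id`, `reason`), `config`.
#' @export
map_eqtls <- function(genotypes, expression, config = eqtl_config(),
                      threads = 1L, verbose = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"),
            inherits(config, "eqtl_config"))
  paired <- pair_samples(genotypes, expression)
  gv <- paired$genotypes$values
  ev <- paired$expression$values
  if (!is.null(config$covariates)) {
    cv <- config$covariates
    if (is.null(colnames(cv)) || !all(paired$samples %in% colnames(cv))) {
      abort("`config$covariates` must have sample ids as colnames covering the shared samples.")
    }
    config$covariates <- cv[, paired$samples, drop = FALSE]
  }
  states <- discretize_expression(ev, t = config$discretize_t)
  expr_t <- t(ev)
  markers <- rownames(gv)
  worker <- function(m) .map_one_marker(m, gv, states, expr_t, config, verbose)
  results <- if (threads > 1L) {
    parallel::mclapply(markers, worker, mc.cores = threads)
  } else {
    lapply(markers, worker)
  }
  names(results) <- markers
  skipped <- purrr::map_dfr(results, function(r) {
    if (is.na(r$skipped)) NULL else tibble(snp_id = r$snp_id, reason = r$skipped)
  })
  if (nrow(skipped) == 0L) skipped <- tibble(snp_id = character(), reason = character())
  records <- purrr::map_dfr(results, "records")
  if (nrow(records) == 0L) {
    records <- tibble(
      snp_id = character(), gene_id = character(),
      relevance_bits = numeric(), mrmr_score = numeric(),
      loocv_accuracy = numeric()
    )
  }
  snp_pos <- .lookup_pos(genotypes$positions, records$snp_id)
  gene_pos <- .lookup_pos(expression$positions, records$gene_id)
  records$cis_class <- classify_cis_trans(snp_pos$chrom, snp_pos$pos,
                                          gene_pos$chrom, gene_pos$pos,
                                          config$cis_window_bp)
  records$distance_bp <- ifelse(
    !is.na(snp_pos$chrom) & !is.na(gene_pos$chrom) & snp_pos$chrom == gene_pos$chrom,
    as.integer(abs(snp_pos$pos - gene_pos$pos)), NA_integer_
  )
  analysed <- results[vapply(results, function(r) is.na(r$skipped), logical(1))]
  structure(
    list(
      table = records,
      ifs = lapply(analysed, `[[`, "ifs"),
      rankings = lapply(analysed, `[[`, "ranking"),
      skipped = skipped,
      config = config,
      n_samples = length(paired$samples)
    ),
    class = "eqtl_scan"
  )
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf(
    "<eqtl_scan> %d record(s) from %d marker(s) analysed (%d skipped), n = %d samples\n",
    nrow(x$table), length(x$ifs), nrow(x$skipped), x$n_samples
  ))
  cls <- table(factor(x$table$cis_class, levels = c("cis", "trans", "ambiguous")))
  cat(sprintf("  cis: %d, trans: %d, ambiguous: %d\n", cls[1L], cls[2L], cls[3L]))
  invisible(x)
}

#' @rdname map_eqtls
#' @param x An `eqtl_scan`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eqtl_scan <- function(x, ...) x$table

#' @rdname map_eqtls
#' @exportS3Method generics::glance
glance.eqtl_scan <- function(x, ...) {
  tibble(
    n_records = nrow(x$table),
    n_markers_analysed = length(x$ifs),
    n_markers_emitting = length(unique(x$table$snp_id)),
    n_markers_skipped = nrow(x$skipped),
    n_cis = sum(x$table$cis_class == "cis"),
    n_trans = sum(x$table$cis_class == "trans"),
    n_ambiguous = sum(x$table$cis_class == "ambiguous"),
    n_samples = x$n_samples
  )
}

#' Compare cis and trans eQTL score distributions
#'
#' One-sided two-sample t-test of the alternative that cis-acting scores
#' are greater on average than trans-acting scores. Ambiguous records are
#' excluded. Welch's unequal-variance form is the default; a pooled-variance
#' form is available via `var_equal`. If both groups are constant the test
#' degenerates and the p-value is 0, 1 or 0.5 by the sign of the mean
#' difference.
#'
#' @param table An eQTL tibble (from [map_eqtls()] or [read_eqtl_table()]),
#'   or an `eqtl_scan`.
#' @param score_field `"mrmr_score"` (default) or `"relevance_bits"`.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return An object of class `cis_trans_summary` with counts
#'   (`n_cis`, `n_trans`, `n_ambiguous`), `t_statistic` and `p_one_sided`.
#' @export
compare_cis_trans <- function(table, score_field = c("mrmr_score", "relevance_bits"),
                              var_equal = FALSE) {
  score_field <- arg_match(score_field)
  if (inherits(table, "eqtl_scan")) table <- table$table
  table <- as_tibble(table)
  n_cis <- sum(table$cis_class == "cis")
  n_trans <- sum(table$cis_class == "trans")
  n_amb <- sum(table$cis_class == "ambiguous")
  if (n_cis < 2L || n_trans < 2L) {
    abort("compare_cis_trans needs at least 2 cis and 2 trans records.")
  }
  cis <- table[[score_field]][table$cis_class == "cis"]
  trans <- table[[score_field]][table$cis_class == "trans"]
  if (stats::var(cis) == 0 && stats::var(trans) == 0) {
    dm <- mean(cis) - mean(trans)
    tstat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm > 0) 0 else if (dm < 0) 1 else 0.5
  } else {
    tt <- stats::t.test(cis, trans, alternative = "greater",
                        var.equal = isTRUE(var_equal))
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(
      n_cis = n_cis, n_trans = n_trans, n_ambiguous = n_amb,
      t_statistic = tstat, p_one_sided = p,
      score_field = score_field,
      mean_cis = mean(cis), mean_trans = mean(trans)
    ),
    class = "cis_trans_summary"
  )
}

#' @export
print.cis_trans_summary <- function(x, ...) {
  cat(sprintf(
    "<cis_trans_summary> %s: cis n = %d (mean %.4f) vs trans n = %d (mean %.4f)\n",
    x$score_field, x$n_cis, x$mean_cis, x$n_trans, x$mean_trans
  ))
  cat(sprintf("  one-sided t = %.3f, p = %.3g (ambiguous excluded: %d)\n",
              x$t_statistic, x$p_one_sided, x$n_ambiguous))
  invisible(x)
}

#' @rdname compare_cis_trans
#' @param x A `cis_trans_summary`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cis_trans_summary <- function(x, ...) {
  tibble(
    score_field = x$score_field,
    n_cis = x$n_cis, n_trans = x$n_trans, n_ambiguous = x$n_ambiguous,
    mean_cis = x$mean_cis, mean_trans = x$mean_trans,
    t_statistic = x$t_statistic, p_one_sided = x$p_one_sided
  )
}
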