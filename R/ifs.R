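#' Incremental feature selection over a ranked gene list
#'
#' Builds the nested prefixes of a gene ranking, scores each prefix with
#' jackknife nearest-neighbour accuracy, and returns the full accuracy
#' curve together with the optimal prefix. Ties on the maximum accuracy are
#' resolved to the smallest prefix length (parsimony). The curve at `k`
#' depends only on the first `k` genes.
#'
#' The curve is computed with an incrementally updated Gram matrix, so the
#' whole sweep costs one rank-1 update and one `n x n` argmax per prefix.
#'
#' @param ranking A [mrmr_rank()] result (`feature_ranking`) or a character
#'   vector of gene ids in rank order.
#' @param features Numeric matrix of continuous expression, samples in rows,
#'   genes in columns (colnames must cover the ranked genes).
#' @param labels Genotype labels, one per sample.
#' @param use Which list of a `feature_ranking` to consume: `"mrmr"`
#'   (default) or `"maxrel"`. Ignored when `ranking` is a character vector.
#' @return An object of class `ifs_result` with fields `curve` (tibble
#'   `k`, `accuracy`), `optimal_k`, `optimal_genes`, `optimal_accuracy`,
#'   and `snp_id` (when available from the ranking).
#' @export
run_ifs <- function(ranking, features, labels, use = c("mrmr", "maxrel")) {
  use <- arg_match(use)
  snp_id <- NA_character_
  if (inherits(ranking, "feature_ranking")) {
    snp_id <- ranking$snp_id
    genes <- switch(use,
      mrmr = ranking$mrmr$gene_id,
      maxrel = utils::head(ranking$maxrel$gene_id, ranking$K)
    )
  } else if (is.character(ranking)) {
    genes <- ranking
  } else {
    abort("`ranking` must be a feature_ranking or a character vector of gene ids.")
  }
  if (length(genes) == 0L) abort("the ranking is empty.")
  if (!is.matrix(features)) features <- as.matrix(features)
  if (is.null(colnames(features)) || !all(genes %in% colnames(features))) {
    abort("`features` must have colnames covering every ranked gene.")
  }
  if (length(labels) != nrow(features)) {
    abort("`labels` must have one entry per sample (row of `features`).")
  }
  n <- nrow(features)
  if (n < 2L) abort("jackknife requires at least 2 samples.")
  x <- features[, genes, drop = FALSE]
  K <- length(genes)
  gram <- matrix(0, n, n)
  acc <- numeric(K)
  for (k in seq_len(K)) {
    gram <- gram + tcrossprod(x[, k])
    nrm <- sqrt(diag(gram))
    if (any(nrm == 0)) {
      abort(sprintf(
        "sample %d has a zero-norm feature vector over the first %d ranked gene(s).",
        which(nrm == 0)[1L], k
      ))
    }
    sim <- gram / (nrm %o% nrm)
    diag(sim) <- -Inf
    pred <- labels[max.col(sim, ties.method = "first")]
    acc[k] <- mean(pred == labels)
  }
  optimal_k <- which.max(acc)  # smallest k attaining the maximum
  structure(
    list(
      curve = tibble(k = seq_len(K), accuracy = acc),
      optimal_k = optimal_k,
      optimal_genes = genes[seq_len(optimal_k)],
      optimal_accuracy = acc[optimal_k],
      snp_id = snp_id,
      list_used = if (is.character(ranking)) NA_character_ else use
    ),
    class = "ifs_result"
  )
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf(
    "<ifs_result>%s K = %d, optimal k = %d, optimal accuracy = %.4f\n",
    if (is.na(x$snp_id)) "" else sprintf(" %s:", x$snp_id),
    nrow(x$curve), x$optimal_k, x$optimal_accuracy
  ))
  invisible(x)
}

#' @rdname run_ifs
#' @param x An `ifs_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ifs_result <- function(x, ...) {
  mutate(x$curve, optimal = .data$k == x$optimal_k)
}

#' @rdname run_ifs
#' @exportS3Method generics::glance
glance.ifs_result <- function(x, ...) {
  tibble(snp_id = x$snp_id, K = nrow(x$curve), optimal_k = x$optimal_k,
         optimal_accuracy = x$optimal_accuracy)
}

#' Plot an incremental-feature-selection accuracy curve
#'
#' @param object An `ifs_result`.
#' @param ... Unused.
#' @return A ggplot object: jackknife accuracy against prefix length, with
#'   the optimal prefix highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.ifs_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = df[df$optimal, ], colour = "red", size = 2) +
    ggplot2::labs(
      x = "number of top-ranked genes",
      y = "jackknife LOOCV accuracy",
      title = if (is.na(object$snp_id)) "IFS curve" else
        paste0("IFS curve: ", object$snp_id)
    ) +
    ggplot2::theme_minimal()
}

#' Write an IFS curve to a two-column TSV (`k`, `accuracy`)
#'
#' @param ifs An `ifs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(ifs, path) {
  stopifnot(inherits(ifs, "ifs_result"))
  readr::write_tsv(ifs$curve, path)
  invisible(path)
}
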