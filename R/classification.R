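#' Cosine distance between two feature vectors
#'
#' `D(v1, v2) = 1 - <v1, v2> / (||v1|| * ||v2||)` where `<,>` is the inner
#' product and `||.||` the Euclidean norm. Ranges over `[0, 2]`; smaller
#' means more similar. Scale-invariant, so genotype prediction is unchanged
#' by positive rescaling of any sample's expression vector.
#'
#' @param v1,v2 Numeric vectors of equal length >= 1 with non-zero norm.
#' @return Cosine distance (scalar).
#' @examples
#' cosine_distance(c(1, 0), c(0, 1)) # orthogonal: 1
#' cosine_distance(c(1, 2), c(-1, -2)) # antipodal: 2
#' @export
cosine_distance <- function(v1, v2) {
  if (length(v1) != length(v2)) abort("`v1` and `v2` must have the same length.")
  if (length(v1) < 1L) abort("vectors must have length >= 1.")
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    abort("cosine distance is undefined for a zero-norm vector.")
  }
  1 - sum(v1 * v2) / (n1 * n2)
}

#' Nearest-neighbour genotype prediction
#'
#' Assigns `query` the label of the training sample minimising
#' [cosine_distance()]. Ties are broken by the smallest training index.
#'
#' @param train Numeric matrix, training samples in rows, features in columns.
#' @param labels Vector of genotype labels, one per training row.
#' @param query Numeric feature vector, length `ncol(train)`.
#' @return The predicted label (same type as `labels`).
#' @export
nna_predict <- function(train, labels, query) {
  if (!is.matrix(train)) train <- rbind(train)
  if (nrow(train) < 1L) abort("at least one training sample is required.")
  if (length(labels) != nrow(train)) {
    abort("`labels` must have one entry per training row.")
  }
  d <- vapply(seq_len(nrow(train)),
              function(i) cosine_distance(train[i, ], query),
              numeric(1))
  labels[which.min(d)]
}

# Row-normalised cosine similarity matrix with zero-norm check.
.cosine_similarity_matrix <- function(features) {
  nrm <- sqrt(rowSums(features^2))
  if (any(nrm == 0)) {
    abort(sprintf(
      "sample '%s' has a zero-norm feature vector; cosine similarity is undefined (degenerate gene selection).",
      if (is.null(rownames(features))) which(nrm == 0)[1L] else rownames(features)[nrm == 0][1L]
    ))
  }
  tcrossprod(features / nrm)
}

.per_class_counts <- function(labels, correct) {
  lev <- sort(unique(labels))
  tibble(
    genotype = lev,
    n_correct = vapply(lev, function(l) sum(correct & labels == l), integer(1)),
    n_total = vapply(lev, function(l) sum(labels == l), integer(1))
  )
}

#' Jackknife (leave-one-out) accuracy of nearest-neighbour genotype prediction
#'
#' Each sample is predicted by the nearest-neighbour classifier trained on
#' the remaining `n - 1` samples; a sample never votes for itself. The
#' overall accuracy aggregates correct predictions over all genotype
#' classes: `ACC = sum_g correct_g / sum_g total_g`.
#'
#' @param features Numeric matrix, samples in rows, selected genes in
#'   columns (continuous expression values).
#' @param labels Genotype labels, one per sample.
#' @return An object of class `jackknife_result` with fields
#'   `overall_accuracy`, `per_class` (tibble: `genotype`, `n_correct`,
#'   `n_total`), `n_samples`, and `predictions`.
#' @export
jackknife_accuracy <- function(features, labels) {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) abort("jackknife requires at least 2 samples.")
  if (ncol(features) < 1L) abort("at least one feature is required.")
  if (length(labels) != n) abort("`labels` must have one entry per sample.")
  singletons <- names(which(table(labels) == 1L))
  if (length(singletons) > 0L) {
    warn(sprintf(
      "genotype class(es) %s have a single sample and can never be predicted correctly under leave-one-out.",
      paste(singletons, collapse = ", ")
    ))
  }
  sim <- .cosine_similarity_matrix(features)
  diag(sim) <- -Inf
  nn <- max.col(sim, ties.method = "first")
  pred <- labels[nn]
  correct <- pred == labels
  per_class <- .per_class_counts(labels, correct)
  structure(
    list(
      overall_accuracy = sum(per_class$n_correct) / sum(per_class$n_total),
      per_class = per_class,
      n_samples = n,
      predictions = pred
    ),
    class = "jackknife_result"
  )
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> n = %d, overall accuracy = %.4f\n",
              x$n_samples, x$overall_accuracy))
  print(x$per_class)
  invisible(x)
}

#' @rdname jackknife_accuracy
#' @param x A `jackknife_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.jackknife_result <- function(x, ...) {
  mutate(x$per_class, accuracy = .data$n_correct / .data$n_total)
}

#' @rdname jackknife_accuracy
#' @exportS3Method generics::glance
glance.jackknife_result <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy, n_samples = x$n_samples,
         n_classes = nrow(x$per_class))
}
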