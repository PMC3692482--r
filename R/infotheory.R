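#' Discretize one gene's expression values into three states
#'
#' Expression values are mapped to three states around the per-gene mean:
#' `-1` below `mean - t * sd`, `+1` above `mean + t * sd`, `0` otherwise,
#' where `sd` is the maximum-likelihood (population) standard deviation,
#' consistent with the plug-in probability estimates used downstream.
#' A constant vector (zero standard deviation) maps to all-zero states.
#' The three-state coding feeds the plug-in mutual-information estimators;
#' the continuous values are kept for classification.
#'
#' @param values Numeric vector of expression values (length >= 2, all finite).
#' @param t Threshold in standard deviations (positive). Default 1.
#' @return Integer vector of states in `{-1, 0, 1}`, same length as `values`.
#' @examples
#' discretize_gene(c(-3, 0, 3))
#' @export
discretize_gene <- function(values, t = 1) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort("`values` must be a numeric vector with at least 2 samples.")
  }
  if (any(!is.finite(values))) {
    abort("`values` contains non-finite entries; expression must be finite.")
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    abort("`t` must be a single positive number.")
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    return(integer(length(values)))
  }
  states <- integer(length(values))
  states[values < m - t * s] <- -1L
  states[values > m + t * s] <- 1L
  states
}

#' Discretize an expression matrix gene-by-gene
#'
#' Applies [discretize_gene()] to each row of a genes-by-samples matrix.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param t Threshold in standard deviations. Default 1.
#' @return Integer matrix of the same shape with entries in `{-1, 0, 1}`.
#' @export
discretize_expression <- function(values, t = 1) {
  if (!is.matrix(values)) abort("`values` must be a matrix (genes x samples).")
  out <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  for (i in seq_len(nrow(values))) {
    out[i, ] <- discretize_gene(values[i, ], t = t)
  }
  out
}

# Canonical-order entropy of a vector of cell counts, in bits.
# Terms are sorted before summation so the result depends only on the
# multiset of counts, making MI exactly symmetric and I(x;x) == H(x).
.entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(0)
  p <- counts[counts > 0L] / n
  sum(sort(-p * log2(p)))
}

# Joint integer code over a list of equal-length discrete vectors.
.joint_code <- function(vs) {
  if (length(vs) == 1L) {
    x <- vs[[1L]]
  } else {
    x <- do.call(paste, c(vs, sep = "\r"))
  }
  match(x, unique(x))
}

.check_discrete_args <- function(vs) {
  if (length(vs) == 0L) abort("at least one vector is required.")
  lens <- lengths(vs)
  if (length(unique(lens)) != 1L) {
    abort("all vectors must have the same length.")
  }
  if (lens[1L] < 1L) abort("vectors must have length >= 1.")
  invisible(NULL)
}

#' Plug-in (maximum-likelihood) joint entropy, in bits
#'
#' Computes `H = -sum p log2 p` over the empirical joint cells of one or more
#' equal-length discrete vectors, with `0 * log 0 = 0`.
#'
#' @param ... One or more discrete vectors of equal length, or a single list
#'   of such vectors.
#' @return Joint entropy in bits (non-negative scalar).
#' @examples
#' entropy_bits(c(0, 0, 1, 1)) # 1 bit
#' @export
entropy_bits <- function(...) {
  vs <- list(...)
  if (length(vs) == 1L && is.list(vs[[1L]]) && !is.data.frame(vs[[1L]])) {
    vs <- vs[[1L]]
  }
  .check_discrete_args(vs)
  code <- .joint_code(vs)
  .entropy_counts(tabulate(code))
}

#' Mutual information between two discrete vectors, in bits
#'
#' Plug-in estimator `I(x;y) = H(x) + H(y) - H(x,y)` on the empirical
#' contingency table. Exactly symmetric in its arguments, and
#' `mutual_information(x, x)` equals `entropy_bits(x)` exactly.
#'
#' @param x,y Discrete vectors of equal length.
#' @return Mutual information in bits (non-negative up to ~1e-12 rounding).
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)) # 1 bit
#' mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)) # 0
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  .check_discrete_args(list(x, y))
  hx <- .entropy_counts(tabulate(match(x, unique(x))))
  hy <- .entropy_counts(tabulate(match(y, unique(y))))
  hxy <- .entropy_counts(tabulate(.joint_code(list(x, y))))
  hx + hy - hxy
}

#' Conditional mutual information, in bits
#'
#' `I(x;y|z) = H(x,z) + H(y,z) - H(z) - H(x,y,z)` on empirical joint
#' distributions. `z` may be a single vector or a list of vectors (several
#' covariates are conditioned on jointly).
#'
#' @param x,y Discrete vectors of equal length.
#' @param z Discrete vector, or list of discrete vectors, same length.
#' @return Conditional mutual information in bits (>= -1e-12).
#' @export
conditional_mutual_information <- function(x, y, z) {
  if (!is.list(z)) z <- list(z)
  .check_discrete_args(c(list(x, y), z))
  hz <- .entropy_counts(tabulate(.joint_code(z)))
  hxz <- .entropy_counts(tabulate(.joint_code(c(list(x), z))))
  hyz <- .entropy_counts(tabulate(.joint_code(c(list(y), z))))
  hxyz <- .entropy_counts(tabulate(.joint_code(c(list(x), list(y), z))))
  hxz + hyz - hz - hxyz
}

# Batched plug-in MI of many coded vectors (rows of `coded`, values 1..nx)
# against one coded vector `yi` (values 1..ny). Same estimator as
# mutual_information(); vectorised over genes for the per-marker loops.
.mi_many <- function(coded, yi, nx, ny) {
  n <- length(yi)
  G <- nrow(coded)
  joint <- (coded - 1L) * ny + matrix(yi, G, n, byrow = TRUE)
  ncell <- nx * ny
  p <- matrix(0, G, ncell)
  for (cell in seq_len(ncell)) p[, cell] <- rowSums(joint == cell)
  p <- p / n
  px <- matrix(0, G, nx)
  for (a in seq_len(nx)) {
    px[, a] <- rowSums(p[, ((a - 1L) * ny + 1L):(a * ny), drop = FALSE])
  }
  py <- matrix(0, G, ny)
  for (b in seq_len(ny)) {
    py[, b] <- rowSums(p[, seq.int(b, ncell, by = ny), drop = FALSE])
  }
  cell_a <- rep(seq_len(nx), each = ny)
  cell_b <- rep(seq_len(ny), times = nx)
  denom <- px[, cell_a, drop = FALSE] * py[, cell_b, drop = FALSE]
  terms <- matrix(0, G, ncell)
  nzero <- p > 0
  terms[nzero] <- p[nzero] * log2(p[nzero] / denom[nzero])
  rowSums(terms)
}

# Fast internal MI for vectors already coded as small positive integers
# (1..nx, 1..ny). Same estimator as mutual_information(), same canonical
# summation order; avoids the generic joint-coding overhead in the per-SNP
# loops.
.mi_coded <- function(xi, yi, nx, ny) {
  joint <- tabulate((xi - 1L) * ny + yi, nbins = nx * ny)
  jm <- matrix(joint, nrow = ny, ncol = nx)
  hx <- .entropy_counts(colSums(jm))
  hy <- .entropy_counts(rowSums(jm))
  hxy <- .entropy_counts(joint)
  hx + hy - hxy
}
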