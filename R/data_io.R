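#' Construct a genotype matrix object
#'
#' A genotype matrix holds F2-intercross marker genotypes coded
#' `1` (homozygous for the first parental allele), `2` (heterozygous),
#' `3` (homozygous for the second parental allele), with `NA` for missing
#' calls. Markers are rows, samples are columns.
#'
#' @param values Integer matrix (markers x samples) with entries in
#'   `{1, 2, 3, NA}`; rownames are marker ids, colnames are sample ids.
#' @param positions Optional tibble with columns `id`, `chrom`, `pos`
#'   (1-based bp) giving marker genomic positions.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, positions = NULL) {
  .check_id_matrix(values, "marker")
  bad <- !is.na(values) & !(values %in% c(1, 2, 3))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "genotype entry %s at marker '%s', sample '%s' is outside {1, 2, 3, NA}.",
      format(values[idx[1L], idx[2L]]),
      rownames(values)[idx[1L]], colnames(values)[idx[2L]]
    ))
  }
  storage.mode(values) <- "integer"
  positions <- .check_positions(positions, rownames(values))
  structure(
    list(values = values, positions = positions),
    class = "genotype_matrix"
  )
}

#' Construct an expression matrix object
#'
#' Continuous expression values with genes in rows and samples in columns.
#' Gene positions are optional; genes without a position drive the
#' `ambiguous` cis/trans class downstream.
#'
#' @param values Numeric matrix (genes x samples), finite entries; rownames
#'   are gene ids, colnames are sample ids.
#' @param positions Optional tibble with columns `id`, `chrom`, `pos`
#'   (transcription start, 1-based bp).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, positions = NULL) {
  .check_id_matrix(values, "gene")
  if (any(!is.finite(values))) {
    abort("expression values must all be finite.")
  }
  storage.mode(values) <- "double"
  positions <- .check_positions(positions, rownames(values), require_all = FALSE)
  structure(
    list(values = values, positions = positions),
    class = "expression_matrix"
  )
}

.check_id_matrix <- function(values, what) {
  if (!is.matrix(values)) abort(sprintf("`values` must be a %s x sample matrix.", what))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort(sprintf("`values` must carry %s ids as rownames and sample ids as colnames.", what))
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf("duplicate %s id: '%s'.", what, rownames(values)[duplicated(rownames(values))][1L]))
  }
  if (anyDuplicated(colnames(values))) {
    abort(sprintf("duplicate sample id: '%s'.", colnames(values)[duplicated(colnames(values))][1L]))
  }
  invisible(NULL)
}

.check_positions <- function(positions, ids, require_all = FALSE) {
  if (is.null(positions)) return(NULL)
  positions <- as_tibble(positions)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(positions))) {
    abort("`positions` must have columns id, chrom, pos.")
  }
  positions <- positions[need]
  if (anyDuplicated(positions$id)) abort("duplicate id in `positions`.")
  positions$chrom <- as.character(positions$chrom)
  positions$pos <- as.integer(positions$pos)
  if (any(is.na(positions$pos)) || any(positions$pos < 1L)) {
    abort("`positions$pos` must be positive 1-based integers.")
  }
  positions
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d markers x %d samples (%d missing calls%s)\n",
    nrow(x$values), ncol(x$values), sum(is.na(x$values)),
    if (is.null(x$positions)) ", no positions" else ", with positions"
  ))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    if (is.null(x$positions)) "no positions" else
      sprintf("%d of %d genes positioned", nrow(x$positions), nrow(x$values))
  ))
  invisible(x)
}

.read_id_table <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  df <- tryCatch(
    utils::read.delim(path, sep = delim, header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      quote = "", comment.char = "", fill = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        abort(sprintf("no data rows in '%s'.", path))
      }
      abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)))
    }
  )
  if (nrow(df) == 0L) abort(sprintf("no data rows in '%s'.", path))
  ids <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- ids
  mat
}

#' Read a genotype matrix from a delimited text file
#'
#' The first row is a header of sample ids, the first column holds marker
#' ids, remaining cells are genotype codes `1`/`2`/`3` or the missing token
#' `NA`. Cells that are not parseable as numbers become missing with a
#' warning reporting the count; numeric values outside `{1, 2, 3}` are a
#' hard error naming the offending cell.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, default tab.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, delim = "\t") {
  mat <- .read_id_table(path, delim)
  suppressWarnings(num <- array(as.numeric(mat), dim = dim(mat), dimnames = dimnames(mat)))
  unparseable <- is.na(num) & !is.na(mat) & !(mat %in% c("NA", ""))
  if (any(unparseable)) {
    warn(sprintf("%d unparseable genotype cell(s) in '%s' set to missing.",
                 sum(unparseable), path))
  }
  out_of_range <- !is.na(num) & !(num %in% c(1, 2, 3))
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "invalid genotype '%s' at marker '%s', sample '%s' in '%s' (must be 1, 2, 3 or NA).",
      mat[idx[1L], idx[2L]], rownames(mat)[idx[1L]], colnames(mat)[idx[2L]], path
    ))
  }
  genotype_matrix(num)
}

#' Read an expression matrix from a delimited text file
#'
#' Same layout as [read_genotypes()] (header of sample ids, first column of
#' gene ids), but every cell must parse as a finite number; any non-numeric
#' cell is a hard error naming the cell.
#'
#' @inheritParams read_genotypes
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delim = "\t") {
  mat <- .read_id_table(path, delim)
  suppressWarnings(num <- array(as.numeric(mat), dim = dim(mat), dimnames = dimnames(mat)))
  bad <- is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "non-numeric expression cell '%s' at gene '%s', sample '%s' in '%s'.",
      mat[idx[1L], idx[2L]], rownames(mat)[idx[1L]], colnames(mat)[idx[2L]], path
    ))
  }
  expression_matrix(num)
}

#' Read a genomic annotation table
#'
#' Three tab-separated columns `id`, `chrom`, `pos` with a header row.
#' Positions must be strict base-10 integers (1-based bp); thousands
#' separators or decimals are rejected. Ids absent from the file are simply
#' unannotated.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `id`, `chrom`, `pos`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "", fill = FALSE)
  if (ncol(df) < 3L) abort("annotation file must have columns id, chrom, pos.")
  names(df)[1:3] <- c("id", "chrom", "pos")
  if (anyDuplicated(df$id)) {
    abort(sprintf("duplicate id '%s' in '%s'.", df$id[duplicated(df$id)][1L], path))
  }
  ok <- grepl("^[0-9]+$", df$pos)
  if (!all(ok)) {
    abort(sprintf("position '%s' for id '%s' is not a plain base-10 integer.",
                  df$pos[!ok][1L], df$id[!ok][1L]))
  }
  tibble(id = df$id, chrom = df$chrom, pos = as.integer(df$pos))
}

.eqtl_cols <- c("snp_id", "gene_id", "relevance_bits", "mrmr_score",
                "loocv_accuracy", "cis_class", "distance_bp")

#' Write an eQTL table to a tab-separated file
#'
#' Columns are written in the fixed order
#' `snp_id gene_id relevance_bits mrmr_score loocv_accuracy cis_class
#' distance_bp`. Records are stably sorted by `snp_id`, preserving the
#' within-marker selection order produced by the pipeline, so the file is
#' deterministic and diffable.
#'
#' @param table eQTL tibble as produced by [map_eqtls()].
#' @param path Output path.
#' @return The input table, invisibly.
#' @export
write_eqtl_table <- function(table, path) {
  table <- as_tibble(table)
  missing_cols <- setdiff(.eqtl_cols, names(table))
  if (length(missing_cols) > 0L) {
    abort(sprintf("eQTL table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  table <- table[.eqtl_cols]
  table <- table[order(table$snp_id), , drop = FALSE]  # stable within-snp order
  readr::write_tsv(table, path, na = "NA")
  invisible(table)
}

#' Read an eQTL table written by [write_eqtl_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with the seven standard eQTL columns.
#' @export
read_eqtl_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  df <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      snp_id = readr::col_character(),
      gene_id = readr::col_character(),
      relevance_bits = readr::col_double(),
      mrmr_score = readr::col_double(),
      loocv_accuracy = readr::col_double(),
      cis_class = readr::col_character(),
      distance_bp = readr::col_integer()
    )
  )
  if (!identical(names(df), .eqtl_cols)) {
    abort(sprintf("'%s' does not have the standard eQTL table columns.", path))
  }
  df
}

.write_id_matrix <- function(values, path, id_col) {
  df <- data.frame(id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  readr::write_tsv(as_tibble(df), path, na = "NA")
  invisible(path)
}

#' Write a genotype matrix to a tab-separated file
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  .write_id_matrix(genotypes$values, path, "marker_id")
}

#' Write an expression matrix to a tab-separated file
#' @param expression An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  stopifnot(inherits(expression, "expression_matrix"))
  .write_id_matrix(expression$values, path, "gene_id")
}

#' Write an annotation table (`id`, `chrom`, `pos`) to TSV
#' @param annotation Tibble with columns `id`, `chrom`, `pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  annotation <- as_tibble(annotation)[c("id", "chrom", "pos")]
  readr::write_tsv(annotation, path, na = "NA")
  invisible(path)
}

#' Pair a genotype and an expression matrix on shared samples
#'
#' Keeps exactly the sorted intersection of sample ids, applied identically
#' to both matrices; samples are always matched by id, never by column
#' order.
#'
#' @param genotypes A [genotype_matrix()].
#' @param expression An [expression_matrix()].
#' @return A list with elements `genotypes` and `expression` restricted to
#'   the shared samples, plus `samples` (the sorted shared ids).
#' @export
pair_samples <- function(genotypes, expression) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"))
  shared <- sort(intersect(colnames(genotypes$values), colnames(expression$values)))
  if (length(shared) < 2L) {
    abort("genotype and expression matrices share fewer than 2 samples.")
  }
  genotypes$values <- genotypes$values[, shared, drop = FALSE]
  expression$values <- expression$values[, shared, drop = FALSE]
  list(genotypes = genotypes, expression = expression, samples = shared)
}
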