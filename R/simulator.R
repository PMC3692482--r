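#' Specification for a synthetic F2-intercross eQTL dataset
#'
#' Describes the study conditions emulated by the generator: an F2
#' population (genotypes segregating 1:2:1 at each marker), markers laid
#' out on a uniform bp grid over several chromosomes with Markov-chain
#' recombination between adjacent markers, continuous expression with
#' planted additive/dominance SNP effects on cis- and trans-located genes,
#' a small-world directed (acyclic) trans-regulatory network propagating
#' centred expression deviations, and i.i.d. Gaussian noise. Defaults
#' follow the published evaluation settings (250 samples, 1000 genes and
#' 1000 markers, small-world topology with average node degree 10).
#'
#' Direct effects are concentrated on "active" markers (eQTL hotspots):
#' planted cis and trans genes are dealt round-robin across the active
#' markers so regulon sizes are balanced. Trans effects are scaled down by
#' `trans_effect_scale`, reflecting the common observation that trans
#' effects are weaker than cis effects.
#'
#' @param n_samples Number of F2 individuals. Default 250.
#' @param n_snps Number of markers. Default 1000.
#' @param n_genes Number of genes. Default 1000.
#' @param n_chromosomes Number of chromosomes; markers are split evenly.
#'   Default 5.
#' @param chrom_length_bp Chromosome length in bp. Default 1e8.
#' @param recomb_fraction Recombination fraction `r` between adjacent
#'   markers, in (0, 0.5]. Default 0.1.
#' @param cis_fraction Fraction of genes given a direct cis effect.
#'   Default 0.10.
#' @param trans_fraction Fraction of genes given a direct trans effect
#'   (gene placed on another chromosome than its marker). Default 0.20.
#' @param prop_active_snps Fraction of markers acting as hotspots carrying
#'   the planted effects. Default 0.05.
#' @param additive_range Range (min, max) of the additive effect magnitude
#'   `a` in expression units (so with the default `noise_sd = 1` these are
#'   effect-to-noise ratios); the sign is random. Default c(1, 3).
#' @param dominance_range Range of the dominance effect magnitude `d`
#'   (heterozygote shift), expression units; sign random. Default c(0, 0)
#'   (no dominance).
#' @param trans_effect_scale Multiplier applied to trans effect sizes.
#'   Default 0.6.
#' @param network_degree Average (undirected) node degree of the
#'   small-world gene network. Default 10. Set to 0 for no network.
#' @param network_rewire_p Watts-Strogatz rewiring probability. Default 0.05.
#' @param network_weight Magnitude of the propagation weight per edge
#'   (sign random); 0 disables propagation. Default 0.2.
#' @param baseline_range Range of per-gene baseline means (log2-intensity
#'   scale). Default c(6, 12).
#' @param noise_sd Residual noise standard deviation (> 0). Default 1.
#' @param cis_window_bp Window used to place cis genes near their marker
#'   (and matching the annotator's default). Default 5e6.
#' @param seed Optional integer seed applied by [simulate_eqtl_dataset()].
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 250L, n_snps = 1000L, n_genes = 1000L,
                            n_chromosomes = 5L, chrom_length_bp = 1e8,
                            recomb_fraction = 0.1,
                            cis_fraction = 0.10, trans_fraction = 0.20,
                            prop_active_snps = 0.05,
                            additive_range = c(1, 3), dominance_range = c(0, 0),
                            trans_effect_scale = 0.6,
                            network_degree = 10L, network_rewire_p = 0.05,
                            network_weight = 0.2,
                            baseline_range = c(6, 12), noise_sd = 1,
                            cis_window_bp = 5e6, seed = NULL) {
  spec <- list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp, recomb_fraction = recomb_fraction,
    cis_fraction = cis_fraction, trans_fraction = trans_fraction,
    prop_active_snps = prop_active_snps,
    additive_range = additive_range, dominance_range = dominance_range,
    trans_effect_scale = trans_effect_scale,
    network_degree = as.integer(network_degree),
    network_rewire_p = network_rewire_p, network_weight = network_weight,
    baseline_range = baseline_range, noise_sd = noise_sd,
    cis_window_bp = cis_window_bp, seed = seed
  )
  if (spec$n_samples < 2L) abort("`n_samples` must be >= 2.")
  if (spec$n_snps < 1L) abort("`n_snps` must be >= 1.")
  if (spec$n_genes < 1L) abort("`n_genes` must be >= 1.")
  if (spec$n_chromosomes < 1L) abort("`n_chromosomes` must be >= 1.")
  if (!(spec$recomb_fraction > 0 && spec$recomb_fraction <= 0.5)) {
    abort("`recomb_fraction` must lie in (0, 0.5].")
  }
  for (f in c("cis_fraction", "trans_fraction", "prop_active_snps",
              "network_rewire_p")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) abort(sprintf("`%s` must lie in [0, 1].", f))
  }
  if (spec$noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (spec$cis_fraction + spec$trans_fraction > 1) {
    abort("`cis_fraction + trans_fraction` must not exceed 1.")
  }
  if (spec$network_degree >= spec$n_genes) {
    abort("`network_degree` must be smaller than `n_genes`.")
  }
  for (f in c("additive_range", "dominance_range", "baseline_range")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || r[2L] < r[1L]) {
      abort(sprintf("`%s` must be a (min, max) pair.", f))
    }
  }
  if (spec$trans_fraction > 0 && spec$n_chromosomes < 2L) {
    abort("trans effects require at least 2 chromosomes.")
  }
  structure(spec, class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %d samples, %d markers x %d genes on %d chromosomes\n",
    x$n_samples, x$n_snps, x$n_genes, x$n_chromosomes
  ))
  cat(sprintf(
    "  r = %g, cis/trans fractions = %g/%g over %g%% active markers, noise sd = %g\n",
    x$recomb_fraction, x$cis_fraction, x$trans_fraction,
    100 * x$prop_active_snps, x$noise_sd
  ))
  invisible(x)
}

# Evenly split n markers across chromosomes (first chromosomes get the
# remainder) and lay them on a uniform bp grid.
.marker_map <- function(spec) {
  per <- rep(spec$n_snps %/% spec$n_chromosomes, spec$n_chromosomes)
  extra <- spec$n_snps %% spec$n_chromosomes
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  purrr::map_dfr(seq_len(spec$n_chromosomes), function(ch) {
    m <- per[ch]
    if (m == 0L) return(NULL)
    grid <- seq(0, spec$chrom_length_bp, length.out = m + 2L)[-c(1L, m + 2L)]
    tibble(chrom = paste0("chr", ch), pos = as.integer(round(grid)))
  })
}

# One gamete per chromosome: a two-state Markov chain along the markers
# with switch probability r between adjacent markers.
.simulate_gametes <- function(m, n, r) {
  start <- stats::rbinom(n, 1L, 0.5)
  if (m == 1L) return(matrix(start, 1L, n))
  switches <- matrix(stats::rbinom((m - 1L) * n, 1L, r), m - 1L, n)
  steps <- rbind(start, switches)
  apply(steps, 2L, cumsum) %% 2L
}

#' Simulate F2-intercross genotypes
#'
#' Each individual carries two gamete haplotypes per chromosome, simulated
#' as independent two-state Markov chains along the marker grid with switch
#' probability `recomb_fraction` between adjacent markers. The genotype at
#' a marker is the allele sum plus one, giving states 1/2/3 with the
#' Mendelian 1:2:1 expectation.
#'
#' Consumes the current RNG state; use [simulate_eqtl_dataset()] for the
#' seeded end-to-end contract.
#'
#' @param spec A [simulation_spec()].
#' @return A [genotype_matrix()] with marker positions attached.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  map <- .marker_map(spec)
  n <- spec$n_samples
  values <- matrix(0L, spec$n_snps, n)
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    m <- length(rows)
    h1 <- .simulate_gametes(m, n, spec$recomb_fraction)
    h2 <- .simulate_gametes(m, n, spec$recomb_fraction)
    values[rows, ] <- h1 + h2 + 1L
  }
  marker_ids <- sprintf("snp%04d", seq_len(spec$n_snps))
  rownames(values) <- marker_ids
  colnames(values) <- sprintf("S%03d", seq_len(n))
  genotype_matrix(values, positions = tibble(id = marker_ids,
                                             chrom = map$chrom, pos = map$pos))
}

# Directed acyclic small-world gene network as an edge list (from, to, w).
.simulate_network <- function(spec) {
  if (spec$network_degree < 1L || spec$network_weight == 0) {
    return(tibble(from = integer(), to = integer(), w = numeric()))
  }
  nei <- max(1L, as.integer(round(spec$network_degree / 2)))
  g <- igraph::sample_smallworld(1L, spec$n_genes, nei = nei,
                                 p = spec$network_rewire_p)
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- pmin(el[, 1L], el[, 2L])
  to <- pmax(el[, 1L], el[, 2L])
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  tibble(
    from = as.integer(from), to = as.integer(to),
    w = spec$network_weight * sample(c(-1, 1), length(from), replace = TRUE)
  )
}

#' Simulate expression with planted cis/trans effects and ground truth
#'
#' Expression of gene g in sample s is
#' `e = mu_g + sum_planted (a * (geno - 2) + d * 1(geno == 2))
#'  + sum_parents w * (e_parent - mu_parent) + N(0, sd^2)`,
#' with one propagation pass over the acyclic small-world network in
#' topological (gene-index) order. Planted cis genes are placed within the
#' cis window of their marker on the same chromosome; planted trans genes
#' are placed on a different chromosome. The returned truth lists only the
#' direct SNP-gene pairs.
#'
#' Consumes the current RNG state; use [simulate_eqtl_dataset()] for the
#' seeded end-to-end contract.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()] (must
#'   carry positions).
#' @param spec The same [simulation_spec()].
#' @return A list: `expression` (an [expression_matrix()] with gene
#'   positions) and `truth` (tibble `snp_id`, `gene_id`, `class`, `a`, `d`).
#' @export
simulate_expression <- function(genotypes, spec) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(spec, "simulation_spec"))
  if (is.null(genotypes$positions)) {
    abort("`genotypes` must carry marker positions.")
  }
  n <- ncol(genotypes$values)
  ng <- spec$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  mu <- stats::runif(ng, spec$baseline_range[1L], spec$baseline_range[2L])

  n_cis <- round(spec$cis_fraction * ng)
  n_trans <- round(spec$trans_fraction * ng)
  n_active <- max(1L, round(spec$prop_active_snps * spec$n_snps))
  active <- sample(rownames(genotypes$values), n_active)
  affected <- sample.int(ng, n_cis + n_trans)
  cis_genes <- affected[seq_len(n_cis)]
  trans_genes <- affected[setdiff(seq_len(n_cis + n_trans), seq_len(n_cis))]

  draw_mag <- function(k, range) stats::runif(k, range[1L], range[2L])
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  truth <- tibble(
    snp_id = c(rep_len(active, n_cis), rep_len(active, n_trans)),
    gene_id = gene_ids[c(cis_genes, trans_genes)],
    class = rep(c("cis", "trans"), c(n_cis, n_trans)),
    a = c(draw_mag(n_cis, spec$additive_range) * rsign(n_cis),
          draw_mag(n_trans, spec$additive_range) * rsign(n_trans) * spec$trans_effect_scale),
    d = c(draw_mag(n_cis, spec$dominance_range) * rsign(n_cis),
          draw_mag(n_trans, spec$dominance_range) * rsign(n_trans) * spec$trans_effect_scale)
  )

  # gene positions
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  gene_chrom <- sample(chroms, ng, replace = TRUE)
  gene_pos <- round(stats::runif(ng, 1, spec$chrom_length_bp))
  mpos <- genotypes$positions
  gene_index <- c(cis_genes, trans_genes)
  for (i in seq_len(nrow(truth))) {
    gi <- gene_index[i]
    mi <- match(truth$snp_id[i], mpos$id)
    if (truth$class[i] == "cis") {
      gene_chrom[gi] <- mpos$chrom[mi]
      offset <- stats::runif(1, -0.9, 0.9) * spec$cis_window_bp
      gene_pos[gi] <- min(max(1, round(mpos$pos[mi] + offset)), spec$chrom_length_bp)
    } else {
      gene_chrom[gi] <- sample(setdiff(chroms, mpos$chrom[mi]), 1L)
      gene_pos[gi] <- round(stats::runif(1, 1, spec$chrom_length_bp))
    }
  }

  # direct effects + noise
  expr <- matrix(mu, ng, n) + matrix(stats::rnorm(ng * n, 0, spec$noise_sd), ng, n)
  for (i in seq_len(nrow(truth))) {
    g <- genotypes$values[truth$snp_id[i], ]
    gi <- gene_index[i]
    expr[gi, ] <- expr[gi, ] + truth$a[i] * (g - 2) + truth$d[i] * (g == 2)
  }

  # one-pass propagation of centred deviations in topological (index) order
  net <- .simulate_network(spec)
  if (nrow(net) > 0L) {
    parents <- split(seq_len(nrow(net)), net$to)
    for (to in sort(as.integer(names(parents)))) {  # topological order
      es <- parents[[as.character(to)]]
      for (e in es) {
        expr[to, ] <- expr[to, ] + net$w[e] * (expr[net$from[e], ] - mu[net$from[e]])
      }
    }
  }
  rownames(expr) <- gene_ids
  colnames(expr) <- colnames(genotypes$values)
  expression <- expression_matrix(
    expr,
    positions = tibble(id = gene_ids, chrom = gene_chrom,
                       pos = as.integer(gene_pos))
  )
  list(expression = expression, truth = truth)
}

#' Simulate a complete seeded eQTL dataset
#'
#' Runs [simulate_genotypes()] then [simulate_expression()] under
#' `spec$seed` (when set), restoring the caller's RNG state afterwards.
#' The same spec (including seed) always produces a bit-identical dataset.
#'
#' @param spec A [simulation_spec()].
#' @return An object of class `eqtl_simulation`: `genotypes`, `expression`,
#'   `truth`, `spec`.
#' @export
simulate_eqtl_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  run <- function() {
    genotypes <- simulate_genotypes(spec)
    ex <- simulate_expression(genotypes, spec)
    structure(
      list(genotypes = genotypes, expression = ex$expression,
           truth = ex$truth, spec = spec),
      class = "eqtl_simulation"
    )
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

#' @export
print.eqtl_simulation <- function(x, ...) {
  cat(sprintf(
    "<eqtl_simulation> %d samples; %d markers, %d genes; %d planted pairs (%d cis, %d trans)\n",
    ncol(x$genotypes$values), nrow(x$genotypes$values),
    nrow(x$expression$values), nrow(x$truth),
    sum(x$truth$class == "cis"), sum(x$truth$class == "trans")
  ))
  invisible(x)
}
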