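# mrmreqtl

Information-theoretic eQTL mapping for experimental crosses: mutual
information + mRMR feature selection + nearest-neighbour genotype
classification under leave-one-out cross-validation.

## The problem

Expression quantitative trait locus (eQTL) analysis links genetic markers to
the genes whose expression they influence. Classical mappers regress each
gene's expression on genotype dose, which captures linear (additive) effects
only. `mrmreqtl` inverts the question: for each marker, the genotype is the
**class label** and gene expression profiles are **features**, and the
"affected genes" are the feature set that best predicts the genotype. Because
the association measure is mutual information on discretized expression, the
method detects non-linear effects — e.g. pure heterozygote (dominance)
shifts that leave the genotype-dose correlation near zero — and the
redundancy penalty suppresses indirectly correlated genes.

The package targets F2 intercross designs (genotypes coded `1`/`2`/`3` for
the two homozygotes and the heterozygote) but runs on any genotype matrix
with 2–3 classes per marker.

## The method

For each marker `s` with genotype vector `h` and genes `e_1 … e_G`
(discretized to 3 states at mean ± t·sd, default t = 1):

1. **Relevance** `D(e_i) = I(e_i; h)` — plug-in mutual information in bits.
   With covariates `z`, `D` becomes the conditional mutual information
   `I(e_i; h | z) = H(e_i, z) + H(h, z) − H(z) − H(e_i, h, z)`.
2. **MaxRel list**: all genes sorted by `D`.
3. **mRMR list**: greedy selection; round `j` picks
   `argmax [ D(e_i) − (1/|S|) Σ_{e_s ∈ S} I(e_i; e_s) ]`
   over unselected genes, `S` the already-selected set (difference scheme;
   quotient scheme available).
4. **IFS**: for each prefix of the chosen list, the genotype of every sample
   is predicted from its nearest neighbour (cosine distance
   `1 − ⟨x, y⟩ / (‖x‖‖y‖)` on continuous expression) trained on the other
   `n − 1` samples; the jackknife accuracy
   `ACC = Σ_g correct_g / Σ_g total_g` traces the IFS curve, and the
   smallest prefix attaining the maximum is the **optimal gene set**.
5. Markers whose optimal accuracy reaches the reporting cutoff (default
   **0.90**) emit one record per optimal gene, annotated **cis** (same
   chromosome, within 5 Mb, inclusive), **trans**, or **ambiguous** (missing
   position).

The package also ships a synthetic F2 generator (Markov-chain recombination
along chromosomes, planted additive/dominance cis/trans effects, an acyclic
small-world trans-regulatory network), a tie-aware precision-recall/AUPR
harness, a hypergeometric enrichment test for affected-gene sets, and a
command-line front end (`inst/cli/mrmr_eqtl.R`) with `run`, `simulate`,
`evaluate` and `enrich` subcommands.

## Worked example

```r
library(mrmreqtl)
library(dplyr)

spec <- simulation_spec(
  n_samples = 120, n_snps = 10, n_genes = 40, n_chromosomes = 3,
  cis_fraction = 0.2, trans_fraction = 0.2, prop_active_snps = 0.3,
  additive_range = c(3, 4), network_degree = 4, seed = 42
)
sim <- simulate_eqtl_dataset(spec)
sim
#> <eqtl_simulation> 120 samples; 10 markers, 40 genes; 16 planted pairs (8 cis, 8 trans)

scan <- map_eqtls(sim$genotypes, sim$expression, eqtl_config(k_rank = 15))
scan
#> <eqtl_scan> 18 record(s) from 10 marker(s) analysed (0 skipped), n = 120 samples
#>   cis: 7, trans: 11, ambiguous: 0

head(tidy(scan), 5)
#>    snp_id  gene_id relevance_bits mrmr_score loocv_accuracy cis_class distance_bp
#> 1 snp0006 gene0035      0.8521732 0.85217319      0.9583333       cis      800316
#> 2 snp0006 gene0014      0.8013501 0.25446196      0.9583333       cis     2203704
#> 3 snp0006 gene0006      0.6858548 0.17021534      0.9583333     trans          NA
#> 4 snp0006 gene0034      0.4732722 0.13604975      0.9583333     trans          NA
#> 5 snp0006 gene0036      0.3062439 0.06140728      0.9583333     trans          NA

compare_cis_trans(scan)
#> <cis_trans_summary> mrmr_score: cis n = 7 (mean 0.5874) vs trans n = 11 (mean 0.0656)
#>   one-sided t = 3.630, p = 0.00511 (ambiguous excluded: 0)
```

Marker `snp0006` explains the genotype of 95.8% of samples out-of-sample
from its optimal gene set; its two cis genes carry the largest relevance
(0.85 and 0.80 bits) and the strongest mRMR scores, and across all emitted
records the cis scores significantly exceed the trans scores (one-sided
Welch p = 0.005) while trans records outnumber cis records — the expected
architecture when planted trans effects are more numerous but weaker.
`autoplot(scan$ifs[["snp0006"]])` draws that marker's IFS curve;
`tidy(scan$rankings[["snp0006"]])` exposes its full mRMR list.

Evaluation against the planted truth uses the MaxRel score over all
marker-gene pairs:

```r
universe <- tidyr::expand_grid(
  snp_id = rownames(sim$genotypes$values),
  gene_id = rownames(sim$expression$values)
)
pr <- precision_recall(maxrel_scores(sim$genotypes, sim$expression),
                       sim$truth, universe)
glance(pr)   # AUPR, number of positives, universe size
```

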