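---
title: "Information-theoretic eQTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic eQTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmreqtl)
```

## The model

`mrmreqtl` maps expression quantitative trait loci by inverting the usual
regression direction: for each marker the genotype is a categorical class
label, and gene expression profiles are the features from which that label
is predicted. A marker's "affected genes" are the feature subset that best
explains its genotype out-of-sample. The per-marker workflow is:

1. **Discretize** each gene's expression into three states at
   `mean ± t·sd` (`t = 1` SD by default). The SD is the maximum-likelihood
   (population) form, consistent with the plug-in probability estimates
   used throughout; a constant gene maps to the all-middle state.
   Discretization exists purely so that mutual information can be estimated
   by contingency-table plug-in; classification later uses the continuous
   values.
2. **Relevance**: `D(e) = I(e; h)` in bits, where `h` is the genotype and
   `I` the plug-in mutual information. With covariates, `D` is the
   conditional mutual information given the (jointly coded) covariates,
   computed from the four-entropy identity
   `I(x; y | z) = H(x,z) + H(y,z) − H(z) − H(x,y,z)`.
3. **mRMR ranking**: greedy forward selection; after the most relevant gene,
   each round maximises `D − R` where `R` is the mean mutual information
   with the already-selected genes (the difference scheme, `mid`). The
   quotient scheme `D / R` (`miq`) is available. The full relevance-sorted
   MaxRel list is kept alongside.
4. **Incremental feature selection (IFS)**: every prefix of the ranked list
   is scored by jackknife (leave-one-out) accuracy of a 1-nearest-neighbour
   classifier under cosine distance on the continuous expression of the
   prefix genes. The optimal gene set is the smallest prefix attaining the
   maximum of the IFS curve.
5. **Reporting**: markers whose optimal accuracy reaches the cutoff
   (default 0.90) emit one record per optimal gene with its relevance, its
   mRMR score (the `D − R` value at its selection round), the marker's
   LOOCV accuracy, and a cis/trans/ambiguous call.

### Why cosine distance, and a degeneracy worth knowing

The nearest-neighbour distance is `1 − ⟨x, y⟩/(‖x‖‖y‖)`: scale-invariant,
so per-sample intensity rescaling does not change predictions. On a single
positive-valued feature, however, every pair of samples has similarity ≈ 1
and the classifier is uninformative — one-gene optimal sets therefore
essentially never pass the accuracy cutoff, and meaningful optima start at
two genes. This is an inherent property of angular distances, not a defect
of the implementation.

### Estimator conventions

All information quantities are plug-in (maximum-likelihood) estimates in
bits, no bias correction. Entropy terms are summed in a canonical (sorted)
order, which makes mutual information exactly symmetric, `I(x; x) = H(x)`
exact, and — importantly for determinism — makes criterion values that tie
in real arithmetic tie exactly in floating point. The greedy argmax treats
values within `1e-9` as tied and takes the earliest gene in input order;
real MI differences on tens-to-hundreds of samples are orders of magnitude
larger, while summation-order noise is orders of magnitude smaller, so the
tolerance only absorbs genuine ties.

### cis / trans / ambiguous

A record is *ambiguous* if the marker or the gene has no genomic position,
*cis* if both lie on the same chromosome with `|snp_pos − gene_start| ≤`
the window (5 Mb by default, inclusive — "within" is read inclusively, and
the gene is anchored at its transcription start), else *trans*. The
cis-versus-trans comparison is a one-sided Welch t-test (pooled-variance
variant available) of the alternative that cis scores exceed trans scores,
on the mRMR score by default; ambiguous records are excluded. If both
groups are constant the test degenerates and the p-value is set by the
sign of the mean difference.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `discretize_t` | 1 | SD | discretization threshold around the gene mean |
| `k_rank` | 50 | genes | mRMR depth carried into IFS; bounds the LOOCV cost while exceeding plausible affected-set sizes |
| `mrmr_scheme` | `mid` | — | difference vs quotient redundancy penalty |
| `ifs_list` | `mrmr` | — | which list IFS consumes (`maxrel` available) |
| `accuracy_cutoff` | 0.90 | proportion | minimum overall LOOCV accuracy to report a marker |
| `cis_window_bp` | 5e6 | bp | inclusive cis distance window |
| `var_equal` | `FALSE` | — | pooled-variance t-test instead of Welch |

Missing genotype calls drop the affected samples for that marker only;
discretization thresholds always come from the full paired cohort. Markers
with fewer than two genotype classes (or fewer than two called samples) are
skipped with a logged reason. The per-marker loop is embarrassingly
parallel and `threads` does not change results.

## The synthetic-data generator

`simulation_spec()` emulates an F2 intercross expression study:

* **Genotypes**: two gamete haplotypes per chromosome simulated as
  two-state Markov chains along a uniform marker grid with switch
  probability `recomb_fraction` (default 0.1) between adjacent markers;
  genotype = allele sum, giving the Mendelian 1:2:1 expectation. Defaults
  (250 samples, 1000 markers × 1000 genes, small-world network of average
  degree 10) follow the published evaluation settings for this class of
  methods; 5 chromosomes of 100 Mb are a plausible desk-scale map.
* **Direct effects**: a `cis_fraction` and `trans_fraction` of genes get a
  planted effect `a·(geno − 2) + d·1(geno = 2)` from one marker. Affected
  genes are dealt round-robin over a `prop_active_snps` subset of markers,
  reflecting eQTL hotspots with balanced regulon sizes. Effect magnitudes
  are drawn from `additive_range`/`dominance_range` in absolute expression
  units with random sign (with the default `noise_sd = 1` they read as
  effect-to-noise ratios); trans effects are scaled by
  `trans_effect_scale = 0.6`, mirroring the common observation that trans
  effects are weaker. Cis genes are placed within the cis window of their
  marker, trans genes on another chromosome, so the planted labels always
  agree with the annotator.
* **Network**: a Watts–Strogatz small-world graph over genes, oriented
  low-to-high index (hence acyclic), propagates centred deviations
  `w·(e_parent − μ_parent)` in one topological pass. Centred propagation
  keeps baselines additive and creates the indirect correlations that the
  redundancy term must filter.
* **Noise**: i.i.d. Gaussian, `noise_sd` (> 0). Baselines are uniform on
  `baseline_range = c(6, 12)`, a log2-microarray-like scale that keeps
  expression positive — which matters for the cosine classifier's geometry.

What the generator does **not** emulate: steady-state network dynamics
(one propagation pass, no feedback), epistasis, sex effects, genotyping
error, probe-level artefacts, and heavy-tailed or heteroskedastic noise.
Passing recovery tests on this generator therefore shows the pipeline's
statistical machinery works under its own model assumptions; it does not
certify performance on real microarray data.

Determinism: `simulate_eqtl_dataset()` applies `spec$seed` (restoring the
caller's RNG state) and the same spec always reproduces a bit-identical
dataset; the two stage functions consume the current RNG stream.

## Evaluation harness

`precision_recall()` requires the candidate-pair universe explicitly —
unscored pairs count as ranked below every scored pair — and computes
tie-aware precision/recall at each distinct score threshold, so the curve
does not depend on within-tie input order. `aupr()` uses step
(average-precision) integration, not the trapezoid, which over-estimates
PR areas. `raupr()` rescales a set of AUPRs by their maximum. Ground truth
is the planted *direct* pairs only; network descendants are deliberately
counted as negatives, which makes reported AUPRs conservative.

`enrich_all()` performs one upper-tail hypergeometric test per marker of
the overlap between its affected genes and a partner list inside a fixed
gene universe; following the original analytical choice, raw p-values are
flagged at 0.05 by default, with BH/Bonferroni adjustment available.

## Study scenarios exercised by the tests

Problem sizes were chosen as desk-scale studies that still have the
statistical structure of interest:

* **Planted-recovery study**: 20 replicates of 250 samples, 50 markers ×
  200 genes, every marker regulating two cis genes with additive effects
  drawn from 3.5–5 noise-SD, no network. Two genes per marker makes the
  optimal prefix provably contain both planted genes whenever the marker is
  emitted (the k = 1 prefix being degenerate, see above); the effect range
  was chosen so that heterozygote/homozygote confusion under cosine-NN —
  the dominant error mode with so few informative genes — stays clear of
  the 0.90 accuracy cutoff.
* **Dominance contrast**: the same design with dominance-only effects;
  heterozygote shifts are uncorrelated with genotype dose (`cov(g, 1(g=2))
  = 0` at 1:2:1 frequencies), so the |Pearson r| baseline collapses to the
  random-ranking floor while MaxRel MI still ranks the planted pairs on
  top.
* **cis > trans study**: 50 replicates of 150 samples, 12 markers × 48
  genes, 4 hotspots each driving 2 cis genes (3.5–4.5 SD) and 4 trans
  genes at 55% of the cis effect size. Replicates yielding fewer than two
  cis or two trans records leave the t-test undefined and are counted as
  failures to reject, not excluded.

`scripts/acceptance.R` reruns reduced versions of these studies end to end
from a single command-line seed and writes the measured quantities as
JSON; all numbers it reports are computed at run time.

## Known limitations

* Plug-in MI is biased upward at small sample sizes; rankings are
  unaffected for comparisons at equal `n`, but absolute bit values should
  not be compared across different sample counts.
* The accuracy cutoff is a hard threshold: markers near 0.90 flicker in
  and out across noise realisations. There is no FDR machinery, by design.
* Cosine-NN cannot use a single gene (see the degeneracy note), and
  all-zero expression vectors over a prefix are an error rather than a
  silently handled case — they indicate degenerate gene selection upstream.
* The covariate-adjusted path replaces relevance by conditional MI but
  leaves redundancy unconditional; with many covariate strata the CMI
  estimate degrades quickly at desk-scale sample sizes.
* `K` (`k_rank`) truncates the mRMR list; an affected set larger than `K`
  cannot be recovered in full.
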