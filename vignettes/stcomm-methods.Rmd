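---
title: "Methods: spatially constrained communication and regulon specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially constrained communication and regulon specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcomm)
```

# Scope and model

`stcomm` analyzes spot-based spatial transcriptomics of serially
sectioned tissue together with (a) per-spot cell-type deconvolution
weights produced upstream, (b) a curated ligand–receptor (L–R) database,
(c) a reference single-cell expression matrix with type labels, and (d)
gene-set collections (regulon target sets, region marker sets, signaling
signatures). Deconvolution itself, regulon discovery, trajectory-based
pseudo-space ordering and clustering are deliberately out of scope: their
outputs are inputs here, which keeps every statistic in this package
directly testable against planted ground truth.

The central claim the pipeline operationalizes is that a communication
event is credible only if three independent lines of evidence agree:

1. **Colocalization** — the two cell types co-occur within spots.
   Weight columns are correlated across all spots (Pearson), tested with
   the two-sided t approximation `t = r√((n−2)/(1−r²))`. This treats
   spots as exchangeable draws; spatial autocorrelation within a domain
   makes the effective sample size smaller than the spot count, so the
   p-values are calibrated for the weight model used in validation
   (independent Dirichlet draws given the domain layout) rather than for
   arbitrarily smooth real tissue.
2. **Spatial co-expression enrichment** — the pair's ligand and receptor
   are co-expressed preferentially in the co-occupied spots. Per spot,
   `R_LR = L(exp)·R(exp)` on log-normalized values
   (`ln(1 + count/total·s)`, `s = 10⁴`); multi-subunit sides are
   aggregated by geometric mean so that one absent subunit nullifies the
   complex (an arithmetic-minimum option exists). Spots are
   cross-classified by occupancy (`X`) and co-expression (`Y = R_LR > 0`)
   and the 2×2 table is tested with the one-sided hypergeometric tail.
3. **Reference communication** — sender cells actually express the
   ligand and receiver cells the receptor. The score
   `prob = L_s·R_r/(kh + L_s·R_r)` is a deliberate simplification of
   full mass-action communication frameworks: it keeps the two essentials
   that can be validated on synthetic data — monotone increase in the
   ligand×receptor mass and saturation governed by `kh` — and drops
   cofactor modulation, trimean summaries and population-size effects.
   Significance comes from a one-sided global label permutation,
   `p = (1 + #{prob* ≥ prob})/(n_perm + 1)`, which never returns 0 and is
   exact under label exchangeability.

A directed (sender, receiver, pair) row is retained iff its unordered
type pair is a network edge, its (edge, pair) row is enriched, and its
permutation test is significant. Both directions of an unordered edge are
evaluated separately; this both-direction reading is our interpretation
of how directed communication maps onto undirected colocalization.

# Regulon and axis statistics

**Activity (RAS).** The area under the gene-rank recovery curve up to
`max_rank = ceil(top_frac·n_genes)`, normalized by its maximum, with
`top_frac = 0.05` by default (configurable; 5% is the customary ceiling
for recovery-curve scoring and is not sensitive for the planted designs
we validate on). The score depends only on ranks, hence is invariant to
monotone transforms. Sparse spot data produce massive zero ties, so ties
are broken by one seeded random permutation of the gene index — a
declared, reproducible rule rather than an arbitrary stable sort.

**Specificity (RSS).** Activity columns and domain indicators are
normalized to probability distributions and compared by base-2
Jensen–Shannon divergence; `RSS = 1 − √JSD`. The square-root conversion
with base-2 logs is the established convention of the JSD-based
specificity score; it maps divergence 0 → RSS 1 and disjoint supports →
RSS 0, and makes RSS scale-invariant in the activity column.

**Connection specificity index.** `CSI(A,B)` is the fraction of all `N`
regulons whose correlation with both `A` and `B` lies strictly below
`P(A,B)` (optionally below `P(A,B) − δ`; `δ = 0.05` appears in parts of
the CSI literature, default 0). The members themselves never count
because `P(A,A) = 1`. Denominator `N` and strict inequalities are fixed
choices; the margin is exposed. Modules are cut from Ward clustering
(`ward.D2`) of Euclidean distances between CSI rows — the linkage is
configurable since only "hierarchical clustering, Euclidean distance" is
inherent to the method; Ward is the default because CSI rows of
co-activated regulons form compact blocks. The default cut of 7 modules
is a convention for embryo-scale atlases and is data-dependent; every
validation here states its own cut.

**Section patterns.** All contiguous section intervals with length in
`[2, n−1]`: singletons and the full run carry no contrast and are the
only exclusion rule consistent with 35 patterns over 9 sections. Pattern
indicators are broadcast to spots (every spot inherits its section's
0/1), so the correlation uses all spots; a section-mean option exists.
A–P genes are the union of the top `top_k = 20` correlations per
pattern, ties broken by gene name.

**D–M–V scoring and selection.** Region gene sets are scored by the
recovery AUC. Binarization offers `zscore` (zero below `z_min = 2.5`)
and `bimodal`, a surrogate for upstream "binary assignment" thresholds:
the midpoint of the two group means of the exact 1-D two-group
least-squares split. A degenerate (constant) score vector cannot be
split and passes through with a warning; under `zscore` it is an error
because the z-score is undefined. D–V genes and regulons use one-vs-rest
two-sided Wilcoxon rank-sum tests (exact by enumeration for combined
n ≤ 12 without ties, normal approximation with tie and continuity
correction otherwise) with BH correction; axis regulons additionally
require maximum activity strictly above `min_max_ras = 0.2`, and A–P
regulons require `|PCC| > 1.5×SD` of all regulon–axis correlations — a
relative threshold, so it adapts to the background correlation level.

**Module scores.** Genes are binned into `n_bins = 24` rank-based bins
of average expression; each signature gene draws up to `n_ctrl = 100`
controls from its bin *without replacement*, and the de-duplicated
control union is subtracted. The without-replacement/unique-union rule
(the convention of the established module-score implementations) makes
the self-control identity exact: when a bin contains only the signature
genes, controls equal the signature and the score is identically zero.
Cell-cycle phase is G1 iff both S and G2/M scores are nonpositive,
otherwise the larger score wins.

# Multiple testing and test families

BH is used wherever an adjusted p-value is required. Family choices the
method itself leaves open are fixed and documented: colocalization
adjusts over all unordered type pairs with finite correlation;
enrichment pools all (edge, pair) rows; D–V selection pools all
(gene, region) or (regulon, region) tests. Fisher sidedness is fixed to
"greater" because the procedure tests enrichment — a recorded
interpretation, as is the per-(pair, L–R)-row contingency reading of the
enrichment step (the alternative, pooling all L–R pairs per edge, would
discard the per-pair verdicts the final filter needs).

# The synthetic atlas

`simulate_spatial_atlas()` generates the study conditions used
throughout validation: by default 4 sections of an 8×8 grid (256 spots,
~the scale of one small dissected region), 6 cell types, 100 genes, two
planted colocalized type pairs hosted in horizontal domain bands that
span sections, and one planted L–R pair per hosted band among 12 decoys.
Weights are Dirichlet per spot (respecting the simplex geometry of
deconvolution output) with concentration boosts of `6·effect_size` for
hosted pairs; counts are negative-binomial (dispersion 2) around
log-normal baselines with multiplicative log-normal noise
(`noise_sd = 0.3`), because Fisher and permutation calibration must hold
under overdispersion, not Poisson noise. Ligand/receptor baselines are
low (0.15 expected counts) so that co-expression is informative;
planted subunits scale with the local sender/receiver weight. The
`gradient` preset (6 sections, 8 genes per consecutive interval, 10
markers per band) plants enough genes per interval that the top-20
selection is exercised at its published default. `effect_size = 0`
yields the null preset for calibration. All generators are pure
functions of (parameters, seed).

What the generator does **not** emulate: spatial autocorrelation beyond
the band structure, transcriptome-wide gene–gene correlation, segmentation
or image artifacts, and realistic gene counts. Passing tests therefore
demonstrate correctness of the statistics under the stated sampling
model and recoverability of planted effects at the stated sizes — not
performance guarantees on real tissue, where correlated noise can
inflate colocalization evidence (see the t-test caveat above).

One consequence of the simplex constraint worth noting: under the null
preset the Dirichlet geometry makes weight columns genuinely
*negatively* correlated, so significantly small q-values for negative
correlations are correct discoveries, not false positives. Calibration
is therefore assessed on the quantity the method reports — the edge rate
(`pcc > 0.06` and `q < 0.05`) — which stays within the nominal band.

# Numerical choices and degenerate inputs

* Thresholds quoted above (`0.06`, `0.85`, `0.2`, `2.5`, `1.5×SD`,
  top 20, 5%) are strict inequalities exactly as stated; boundary cases
  are excluded, except weight binarization which is `≥ threshold`
  (documented, boundary inclusive) with default 0.1 when no upstream
  confident-call table is supplied.
* Zero-variance weight or activity columns are excluded from
  correlation-based statistics with a log entry; all-zero activity
  columns yield NA specificity.
* Geometric means treat any zero subunit as zero (`exp(mean(log))` with
  `log(0) = −∞`).
* Odds ratios use the sample cross-product with `Inf`/`NaN` conventions
  for zero cells; p-values never depend on them.
* Probability-vector validation tolerates `1e−9` in the sum; weight row
  sums tolerate `1e−6` above 1.
* Logging is level-based (`st_log_level()`); every stage reports shapes,
  parameters and the counts surviving each filter.

# Validation design and problem sizes

The test suite builds every fixture in code. Oracles are independent
re-derivations: hypergeometric enumeration via `choose()` ratios for the
Fisher test (exhaustive over all 135,751 tables with total ≤ 40),
complete label-assignment enumeration for the rank-sum test (all
tie-free inputs with combined n ≤ 10), a triple-loop count for CSI, the
step-up definition for BH, literal step-curve integration for the
recovery AUC, and hand-derived Jensen–Shannon values. Stochastic
properties use fixed seed grids: 100 null atlases × 50 L–R pairs × 200
permutations for calibration; 25 seeds for end-to-end recovery of
planted triples; 25 seeds for axis-gene and axis-regulon recovery;
40 null seeds for the colocalization edge rate. These sizes are the
package's validation design, chosen to give binomial standard errors
small enough for ±3·SE bands around the nominal 5% level.

# Known limitations

* The communication probability is a simplified score; rankings can
  differ from full mass-action frameworks when cofactors or population
  sizes matter.
* Colocalization is strictly within-spot; neighborhood-window or
  spatial-lag colocalization is out of scope.
* The correlation t-test and the Fisher test assume exchangeable spots;
  strong spatial smoothness beyond the modeled domain structure will
  make them anti-conservative.
* Pseudo-space ordering is consumed, never computed; when absent, the
  documented fallback is section order with within-section array row.
* QC filtering (minimum detected genes, mitochondrial fraction) is
  provided as optional preprocessing and is not part of any tested
  pipeline stage.
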