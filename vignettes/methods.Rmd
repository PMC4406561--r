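---
title: "Models and methods behind countnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind countnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

countnet implements the bespoke computational stages of a progressive
RNA-seq mining protocol: counting from unique mappers, consensus voting of
differentially expressed (DE) genes, Fisher-exact GO enrichment with a
Cochran–Mantel–Haenszel (CMH) pre-check, and regulatory module-network
learning. This vignette explains each model, its assumptions, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate. Everything asserted here
is computed by the package's tests or examples; nothing is an external
empirical claim.

## 1. Read classification and counting

**Model.** A read is a set of reported placements. Classification is at
the read level, in strict precedence: unmapped → *failed*; QC-flagged or
below the mapping-quality threshold → *filtered*; one placement →
*unique*; several → *multi*. Only unique reads are counted, so the
library size used in every normalization is the number of uniquely mapped
reads. The four categories partition the reads, which gives the
conservation identity `unique + multi + failed + filtered = total` that
the `mapping_stats()` constructor enforces, and the mapped percentage
`100·(unique+multi)/total` rounded **half-up** to two decimals — base R's
`round()` is round-half-even and would flip exact `.xx5` ties relative to
conventional mapping reports.

Multiplicity comes from the SAM NH tag when present, otherwise from
read-id multiplicity across mapped lines, which makes the inference
order-independent (a tested property). The filtered category is the
package's own operationalization — QC flag 0x200 or mapping quality below
a threshold that defaults to 0, i.e. no quality filtering unless asked —
because the protocol's report format includes such a column without
defining it.

**Counting.** Read–exon compatibility is ≥ 1 bp interval overlap; no
spliced-junction modelling (that belongs to the aligner). A read
overlapping exons of more than one gene is discarded and tallied
ambiguous, in the spirit of union-mode counters. For reads compatible with
several isoforms of one gene, three rules are provided:
`total_to_each_isoform` (+1 to every compatible isoform — the protocol's
characteristic choice), `discard_ambiguous` (+1 only when exactly one
isoform is compatible), and `proportional` (+1/n each). Gene-level counts
are rule-invariant by construction, and under the proportional rule
isoform counts sum to the number of assigned reads; both are tested
properties.

**Expression units.** RPKM uses the union of all exon intervals of a gene
across isoforms as the length denominator; per-isoform values use the
isoform's own exonic length. Depth-normalized values are `count /
library_size`, averaged arithmetically over a sample's replicates.
Coordinates are 0-based half-open internally, converted once at the SAM
(1-based) and GTF (1-based inclusive) boundaries; write–read round trips
are tested.

## 2. Consensus differential expression

Per-method result lists enter as tables of (gene, p, optional q, optional
log2 fold change). Benjamini–Hochberg adjustment is the step-up
`q_(i) = min_{j≥i} p_(j)·n/j` clipped to 1 (delegated to `p.adjust`,
verified against a brute-force implementation to 1e-12). The selection
cut-off (default 0.05) is **inclusive** (≤), matching the conventions of
the usual DE packages; one global criterion — p or q — applies to all
lists. A gene joins the consensus when it appears in at least
`min_support` lists (default 3, the usual at-least-3-of-5 overlap rule;
configurable because the protocol hedges). `min_support = m` is set
intersection, `= 1` is union, and membership is monotone in both the
threshold and the support level (tested).

**Suitability check.** Count-based normalization assumes most genes are
similarly expressed in both conditions. The check computes per-gene
|log2| ratios of depth-normalized condition means with a pseudo-count of 1
and passes iff the fraction of genes exceeding `assumption_fc` (default
|log2 FC| > 2) is strictly below `assumption_fraction` (default 0.5). The
protocol states no statistic, so both knobs are config keys; the boundary
case (exactly half the genes discordant) fails.

**Built-in test.** So the pipeline can run with no external DE package, a
pooled two-library exact binomial test is included: summed within
condition, `x1` of `x1+x2` successes at probability `N1/(N1+N2)`,
two-sided, with `x1+x2 = 0` giving p = 1 and a flag. It is labelled
plumbing deliberately: it models **no biological dispersion**, so it is
approximately calibrated only for homogeneous (cell-line-like) replicates
and grows anti-conservative as dispersion rises — which is exactly why the
real protocol delegates DE calling to dispersion-aware external methods.

## 3. GO enrichment

For each term with at least one DE gene, the 2×2 table is (DE with term,
DE without, background with, background without), the background being the
measured-gene universe minus the DE set — all genes with observed
expression, not the whole genome, per standard practice. Fisher's exact
test is two-sided by default (matching the convention of the R function
this protocol names), with one-sided "greater" available since enrichment
is directional. Terms are ranked by ascending p within each of the three
ontology categories, ties broken by term id; no multiple-testing
correction is applied to enrichment p-values (the ranking is on raw p),
though BH is available separately.

The CMH pre-check runs on the term-membership × DE-status tables
stratified by the three categories:
χ² = (|Σₖ(aₖ−Eₖ)|−½)²/ΣₖVₖ with Eₖ = r₁ₖc₁ₖ/nₖ,
Vₖ = r₁ₖr₂ₖc₁ₖc₂ₖ/(nₖ²(nₖ−1)), 1 df. Two deliberate choices: the strata
are the three GO categories (the protocol never defines them), and the
gate is **advisory** — the p-value is attached and logged, never used to
drop terms — because the protocol's stated interpretation of the MH
p-value inverts the usual rejection logic, so silently acting on either
reading would be irreversible. One numerical note: the ½ continuity
correction is subtracted unconditionally before squaring, which is what
the formula above says and what the balanced-table worked example
(statistic 0.0975 on a single (10,10,10,10) stratum) requires; R's stock
implementation skips the correction when |Σ(aₖ−Eₖ)| < 0.5, so the two
agree everywhere except in that near-null zone (and exactly agree with the
correction off).

## 4. Regulatory module networks

**Model.** A module is a set of co-expressed genes plus a binary decision
tree over TF expression. Internal nodes test `TF < threshold` (left)
versus `≥` (right); leaves model all member-gene expression values over
the leaf's conditions as one Gaussian with ML mean and variance, floored
at `var_floor = 1e-6`. The pooled (per-leaf, not per-gene) variance is a
deliberate choice from the module-networks tradition the method derives
from; the protocol itself never states the likelihood. A gene's
log-likelihood under a tree is the sum over conditions of the log normal
density at the routed leaf.

**Fitting loop.** Non-TF DE genes are clustered by K-means on gene-wise
z-scored profiles (z-scoring only for clustering; trees model the
untransformed input scale, which the pipeline sets to log2(RPKM+1) per
replicate). Default K = max(2, ⌊n/20⌋) capped at 10 — the protocol gives
no K, and about 20 genes per module matches the module sizes it
showcases. Then, until the relative change in total log-likelihood drops
below `rel_tol = 1e-6` or `max_iter = 100`: fit one tree per module
(greedy top-down; candidate thresholds are midpoints between consecutive
distinct TF values at the node; split only on positive pooled-Gaussian
likelihood gain; depth capped at `max_depth = 3`), then reassign every
gene to its argmax module, ties to the lowest module id.

**Monotonicity.** Each refit keeps the better of the fresh greedy tree and
the previous structure with leaf parameters re-estimated on the new
members. Routing depends only on TF profiles, which never change, so
re-estimation is exact constrained ML and cannot lose likelihood;
reassignment is an argmax. The recorded log-likelihood trace is therefore
non-decreasing — an EM-style guarantee the tests check on 20 seeded
fixtures — with one exception: modules shrinking below `min_module_size`
(default 2) are dissolved and their members redistributed, which can dip
the likelihood. TF "selection" is simply whichever TFs the greedy splits
use; the low/medium/high phrasing in module displays is treated as display
discretization, not as a modelling commitment.

**Scores and export.** The module score is the mean pairwise Pearson
correlation of member profiles (singleton modules score 1.0, flagged;
zero-variance pairs contribute 0, flagged). Correlation to the module mean
profile was the alternative reading; mean pairwise was chosen and cannot
be disambiguated against the protocol's printed 0.85 because that value
comes from external data. The exported network takes the top modules by
score and emits one edge per (TF used in the tree) × (member gene),
self-edges dropped; the edge count equals Σ|TFs|·|members| by a
brute-force double loop in the tests.

## 5. Synthetic data: what a green test establishes

The generators are pure functions of their seed (byte-identical outputs,
tested) and return ground truth alongside the data.

* `simulate_annotation`: 1 toy chromosome, two-exon genes (exons ≥ 100 bp,
  so a 50 bp read sits inside one exon), a configurable subset with a
  second isoform sharing exon 1 — enough to exercise every counting rule,
  not a model of real gene structure.
* `simulate_alignments`: category counts are an **exact** deterministic
  partition of `n_reads` (rates rounded, remainder unique), so
  classification tests are exact rather than stochastic. Multi-mappers get
  two placements with `NH:i:2`. No sequences, qualities, errors, or
  spliced reads are modelled.
* `simulate_counts`: per-gene means log-normal (median 20, log-sd 1);
  counts negative binomial with variance μ + φμ²; DE genes shifted by
  ±`de_log2fc` in condition 2. The default dispersion φ = 0.005 models
  homogeneous cell-line replicates and was fixed a priori from the
  calibration analysis of the built-in binomial test (inflation factor
  ≈ 1 + φμ ≈ 1.2 at these means, predicted type-I ≈ 0.07 at α = 0.05,
  within the documented ≤ 0.08 anti-conservative tolerance). At
  biological-tissue dispersions (φ ≥ 0.05) the built-in test would not be
  calibrated — by design, see §2.
* `simulate_go`: one planted term covering DE genes at high probability
  plus uniform decoys over all three categories.
* `simulate_regulatory`: TF profiles i.i.d. standard normal per condition;
  each module's condition means follow a ground-truth depth-≤2 median
  threshold tree over its own TFs with adjacent leaf means spaced
  `leaf_sep`·σ apart; members are means + N(0, σ²). Planted-module
  recovery (ARI ≥ 0.9 at 3σ separation across 10 seeds) therefore
  certifies the fitting loop on data matching the model's own assumptions
  — it says nothing about model misspecification, TF post-transcriptional
  regulation, or condition dependence, none of which are emulated.

## 6. Numerical and interface choices

* Errors are classed conditions (`countnet_format_error`,
  `countnet_no_tf_error`, ...) so callers and the pipeline can react
  specifically; the no-TF condition skips the network stage with a logged
  reason instead of failing the run.
* All persisted outputs are deterministically sorted TSVs; with a fixed
  seed, re-running the pipeline reproduces byte-identical files (tested).
* The pipeline applies the web-style stage-selection rule: choosing a
  stage runs all earlier stages automatically, each persisting its outputs
  before the next starts.
* Thresholds compare inclusively; consensus ordering breaks ties by gene
  id; enrichment ranking by term id; reassignment by lowest module id —
  every ordering has a deterministic tie-break.

## Known limitations

No junction-aware or strand-aware counting; no isoform-abundance
estimation beyond the simple proportional rule; the built-in DE test is
plumbing, not a dispersion-aware method; GO annotations are used as given
(no ancestor propagation); network edges carry no statistical
significance; BAM input is out of scope (SAM text is the supported,
hand-writable interchange).
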