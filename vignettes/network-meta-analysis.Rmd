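---
title: "Network-based meta-analysis of multi-study aging transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based meta-analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingMetaNet)
```

# The problem

Individual microarray studies of the aging human frontal cortex are small
and noisy: a gene significantly associated with age in one cohort is often
missed in another, and the cross-study overlap of significant genes is tiny
relative to each per-study list. agingMetaNet implements the integration
strategy that addresses this: harmonize several independent studies into a
compendium, combine per-study differential-expression evidence with three
complementary meta-analysis methods, and then move from gene lists to
biology by projecting the consensus genes onto a protein–protein interaction
(PPI) network where hub genes and densely connected modules can be ranked
and tested.

Every stage is exercised end-to-end on synthetic compendia with planted
ground truth, so the pipeline's operating characteristics (recall of planted
effects, false-positive rates, calibration of the combined statistics) are
measured rather than assumed.

# The model, stage by stage

## Study harmonization

Each study is a genes × samples matrix with sample ages. Samples are
classified as *young* (20–40 years) or *old* (60–90 years); ages in the gap
are excluded, and a study is kept only when both groups retain at least
three samples. Probe-level data are collapsed to one row per gene (mean by
default, median by option). The meta-analysis universe defaults to the
**intersection** of per-study gene sets, because every combination method
needs a per-study p-value for each tested gene; a union mode keeping genes
measured in ≥ k studies is available, with the missing studies skipped and
degrees of freedom reduced gene-wise. Whether a published compendium of this
kind used an intersection or a coverage-thresholded union is generally not
recoverable from reported totals, so the choice is explicit configuration.

Raw-intensity data are normalized by a generalized-log transform followed by
quantile normalization. The glog transform

$$\mathrm{glog}_2(x) = \log_2\!\frac{x + \sqrt{x^2 + c^2}}{2}$$

behaves as $\log_2 x$ for $x \gg c$ and remains defined at zero
($\mathrm{glog}_2(0) = \log_2 c/2$), providing the variance-stabilizing
contract of a VSN step in closed form; $c$ defaults to the 5th percentile of
the positive intensities. A full maximum-likelihood VSN fit is deliberately
out of scope — the closed form is monotone, testable, and sufficient for the
role the step plays here. Quantile normalization (via limma, tie-averaged)
makes all per-sample empirical distributions identical and is exactly
idempotent.

## Per-study differential expression

Each study is analysed with an empirical-Bayes moderated t-test for the
two-group design. Per-gene residual variances $s^2_g$ (df $d$) are shrunk
toward a prior $s_0^2$ with prior df $d_0$:

$$s^2_{\mathrm{post},g} = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},\qquad
  \tilde t_g = \frac{\bar x_{\mathrm{old},g} - \bar x_{\mathrm{young},g}}
  {s_{\mathrm{post},g}\sqrt{1/n_1 + 1/n_2}},$$

with $\tilde t_g$ referred to a t-distribution on $d + d_0$ df. The
hyperparameters are estimated by method of moments on $\log s^2_g$ with the
trigamma inversion solved by Newton iteration (tolerance $10^{-8}$, at most
50 steps); estimated $d_0$ above $10^6$ is treated as infinite (full
shrinkage). Two limits anchor the implementation: $d_0 = 0$ reproduces the
ordinary two-sample t-test exactly, and when all gene variances coincide the
posterior variance is common to all genes and $\tilde t$ matches $t$ up to
the small-sample factor $\exp\{(\log(d/2) - \psi(d/2))/2\}$ of the
log-scale moment estimator, which vanishes as $d$ grows — the same behavior
as the reference implementation in limma, against which the estimator is
cross-checked in the test suite. Genes with zero variance in both groups are
reported with $p = 1$ and a warning rather than an error.

Per-study significance defaults to p < 0.05 **and** BH-FDR < 0.05; because
published workflows of this kind do not always state whether the FDR filter
was applied per study, both thresholds are exposed (`alphaFdr = 1` disables
the FDR filter; the pipeline default) and logged.

## Three-method meta-analysis and consensus

For every universe gene:

* **Fisher's method**: $X = -2\sum_k \ln p_k \sim \chi^2_{2k}$. Exact zeros
  are clamped to the smallest positive double with a warning; missing
  studies reduce the df. For one study the combination is the identity.
* **Fixed-effect model**: inverse-variance pooling of the per-study log2
  effects, $w_k = 1/SE_k^2$, pooled effect $\sum w_k e_k / \sum w_k$, pooled
  SE $1/\sqrt{\sum w_k}$, with Cochran's
  $Q = \sum w_k (e_k - \hat e)^2 \sim \chi^2_{k-1}$ as the heterogeneity
  check. The effect is the raw log2 mean difference (a standardized option
  is not offered; the raw difference is what the per-study moderated fit
  estimates).
* **Vote counting**: the number of studies with p below the per-study
  threshold (0.05); a direction-consistent variant counting only
  majority-sign studies is available.

The consensus rule follows the convention of combined p < 0.001 for Fisher
and the fixed-effect model and votes ≥ 2, with consensus = all three.
(Where a source describes the vote rule with both "< 2" and "≥ 2" wording,
the ≥ 2 reading is implemented — it is the one consistent with reported
consensus counts.) Direction is the sign of the pooled fixed-effect
estimate; genes whose per-study signs disagree while |pooled z| < 1.96 are
labeled *discordant* rather than given a spurious direction. The 1.96 floor
is the conventional two-sided 5% point; it only affects labeling, never
membership of the consensus list.

## Zero-order PPI network, hubs, and modules

Consensus genes seed a **zero-order** network: the induced subgraph on the
seed genes only, keeping edges with STRING-convention combined score ≥ 900
(the 0.9 high-confidence cutoff on the 0–1000 integer scale; the boundary
score 900 is retained so that synthetic edge scores drawn from 900–999 all
pass). Isolated seeds are reported, not silently dropped.

Degree centrality (DC) is the node's edge count; betweenness centrality
(BC) is unnormalized Brandes shortest-path betweenness on the undirected,
unweighted graph, each unordered pair counted once. **Hubs** are nodes with
DC ≥ 10 ranking in the top 10% — the denominator being the full consensus
list, not just the genes that entered the graph. The ranking sorts on BC
with DC and then gene ID as tie-breakers, making the ordering total and
invariant to input row order; both the metric and the thresholds are
configurable.

Connected components are enumerated; the largest ("continent") is
partitioned by deterministic greedy-modularity (CNM) community detection
(walktrap available by flag). Every candidate — continent community or
smaller component ("island") — with ≥ 5 genes receives a permutation
p-value: `nPerm` random node sets of the same size are drawn from the
continent with degree-binned matching (5 quantile bins by default), and

$$p = \frac{1 + \#\{\text{null internal edge count} \ge \text{observed}\}}
  {n_{\mathrm{perm}} + 1},$$

so the resolution floor is $1/(n_{\mathrm{perm}}+1)$ and a warning is
issued when `nPerm` is too small for the requested level. Modules with
p < 0.05 are reported.

**A caveat on module p-values.** The permutation p is valid for a gene set
chosen *independently* of the graph's edge density — for random continent
node sets its distribution is uniform (this is tested). Candidate modules,
however, are produced by modularity *maximization*, which by construction
selects sets denser than degree-matched random sets; on unstructured random
graphs detected communities therefore still receive small p-values. The
module p should be read as "this gene set is more internally connected than
degree-matched chance", not as a test of whether community structure exists
at all. The null model behind module significance in the web tools this
workflow emulates is undocumented; this explicit permutation definition is
our stand-in and is labeled as such in outputs.

## Enrichment

Over-representation uses the one-sided hypergeometric upper tail on the
2×2 table of query × set membership over a background, with fold enrichment
$(a/(a+b)) / ((a+c)/N)$ and BH FDR across sets. The background defaults to
the tested gene universe, not the whole genome — enrichment against genes
that could never have been called is not meaningful. DAVID's EASE variant
(penalizing the overlap by one) is available by flag but is not the
default; the unpenalized tail is exact and is verified against explicit
enumeration to ~1e-15. Reference-set enrichment (e.g. a curated aging-gene
database) reports the odds ratio with a Woolf 95% CI,
$\exp\{\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\}$, a two-sided Fisher exact
p, and the Haldane–Anscombe +0.5 correction (flagged) when a cell is zero.
Gene sets are flat (GMT); ontology-graph propagation is out of scope.

## Follow-up statistics

qPCR fold changes use the 2^-ΔΔCt convention with the control-group mean as
calibrator: ΔCt = Ct(target) − Ct(reference) per sample,
ΔΔCt = ΔCt − mean(control ΔCt), fold = 2^−ΔΔCt; groups are compared by a
t-test on the ΔCt scale, where the model is linear. The per-sample-offset
invariance (adding any constant to a sample's target and reference Ct
leaves everything unchanged) holds exactly and is tested.

Spearman correlation with age uses midranks; the p-value is the
t-approximation, replaced by an exact full-enumeration permutation p for
n ≤ 8 without ties (8! = 40,320 orderings; enumerating 10! in pure R costs
more than the accuracy gain, so 8 is the package's exact-mode cutoff).
The two agree within 0.05 at n = 8, which is tested.

# The synthetic-data generator

The generator emulates the structure of a multi-study frontal-cortex aging
compendium: a shared gene universe, per-study young/old groups with ages
drawn uniformly within 20–40 and 60–90 (the 41–59 gap is never generated in
the two-group design; a continuous-age mode exists for age-correlation
follow-ups), per-study per-gene batch offsets, and planted up/down genes
whose old-group mean shifts by ±δ on the log2 scale. Defaults are chosen to
be realistic for the emulated setting: 5 studies, 2000 genes, 15 samples
per group, 10% up + 10% down planted genes at δ = 1.0 log2 units, batch sd
0.5, unit residual noise. Expression is simulated directly on the log2
scale; a raw-scale mode exponentiates and adds multiplicative noise so the
normalization path can be exercised. The scored interaction generator is a
planted-partition graph (within-community probability `intraP`, between
`interP`, scores uniform on 900–999 so all synthetic edges pass the default
threshold), with optional hub over-wiring to a target degree. The qPCR
generator shifts the treated-group target Ct by −log2(fold) so the ΔΔCt
arithmetic inverts it exactly at zero noise.

What the generator does **not** emulate: probe-level artifacts, platform
differences, correlated gene-gene expression beyond the planted groups,
non-Gaussian heavy-tailed noise, confounding of age with batch, and the
biological coupling between differential expression and PPI topology. A
passing planted-truth test therefore demonstrates the statistical machinery
recovers known signal under idealized conditions; it does not certify
performance on real arrays.

# Numerical and design choices

* Trigamma inversion: Newton with analytic derivative (`psigamma(., 2)`),
  tolerance 1e-8, ≤ 50 iterations; inputs below 1e-8 map to an infinite
  prior df.
* BH adjustment delegates to `stats::p.adjust`; Fisher/χ², t and normal
  tails use the stats distribution functions; graph algorithms use igraph.
  The meta-analytic statistics, the moderated-t estimator, the permutation
  test and the enrichment arithmetic are implemented here and cross-checked
  in the tests against independent oracles (explicit enumeration, matrix
  -power path counting, limma, metafor).
* Hub tie-breaking: BC desc, then DC desc, then gene ID — a total order, so
  results cannot depend on input row order.
* Module recovery scoring: community detection may reassign a single
  boundary node of a planted module; recovery is therefore assessed on the
  best-matching (majority-overlap) reported module in the acceptance
  summary, while the fixed demonstration fixture asserts full containment.
* Degenerate inputs: constant expression rows get p = 1 with a warning;
  constant columns survive quantile normalization by rank-averaging; empty
  networks and empty consensus lists are reported conditions, not crashes.
* All randomness is seeded; generation and the permutation test are
  bit-reproducible given the seed, and the pipeline manifest records output
  checksums so a rerun can be verified byte-for-byte.

# Problem sizes used in the shipped checks

The test suite and the acceptance summary run entirely on synthetic data:
the planted-recovery compendium uses 5 studies × 2000 genes × 30 samples;
null-calibration sweeps use 100 seeds of 2000-gene compendia (5 samples per
group) for the Fisher null and 100 × 1000-gene draws for Cochran's Q;
betweenness is verified on 200 random graphs of ≤ 12 nodes against
exhaustive path counting; the permutation-module demonstration uses a
planted 5-clique in a 100-node background at 999 permutations. These sizes
were chosen so the full statistical battery runs in minutes on a laptop
while keeping Monte-Carlo error well below the asserted margins.

# Known limitations

* The VSN step is the closed-form glog approximation, not the
  maximum-likelihood affine-calibrated fit.
* Fixed-effect only; no random-effects model (heterogeneity is *reported*
  via Q, not modeled).
* Flat gene-set ORA; no GO-graph topology handling.
* Module significance inherits the selection-bias caveat above.
* Two-group design without covariates; no batch correction beyond the
  per-study normalization contract.
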