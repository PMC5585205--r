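---
title: "Models and methods behind powerggm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind powerggm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerggm)
```

powerggm implements the analysis chain of an inflammatory-response
expression study: a two-condition (stimulus vs vehicle) by multi-time-point
factorial microarray design on isolated microglia, followed by
co-expression network inference, protein-interaction module detection, and
genetic association for candidate genes. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where the methodology was genuinely open.

## The synthetic study and what it does (not) emulate

Every stage is validated against simulated data with recorded ground truth
(`sim_config()`, `gen_all()`). The generator emulates:

* a balanced factorial design (2 conditions × 4 postnatal time points ×
  `n_samples_per_cell` replicates) on a log2 intensity scale, with four
  planted response clusters — up- and down-regulated at each of the first
  two time points, mirroring an immediate and an early inflammatory wave;
* gene–gene conditional dependence through a sparse precision matrix
  Ω built on a planted graph (scale-free, small-world, or hub-star);
  expression is multivariate normal with covariance Ω⁻¹;
* a protein interactome that is the disjoint union of a star K(1, s), a
  complete bipartite module K(a, b), and a configuration-model background
  with a prescribed sparse degree sequence (60% degree 1, 30% degree 2,
  10% degree 3; self-loops and multi-edges rejected);
* annotation categories covering 80% of each planted module plus equal
  background padding, and a TF target set covering 60% of the star;
* Hardy–Weinberg genotypes with per-SNP MAF uniform on `maf_range`, a
  phenotype responding to minor-allele *presence* at one causal SNP
  (β per carrier, unit Gaussian noise), and an expression trait responding
  additively to one cis-eQTL (γ per allele count).

It deliberately does **not** model probe effects, dye bias or other
microarray noise, linkage disequilibrium between SNPs, or any spatial/image
component of the phenotype (the phenotype is one scalar per subject, a
white-matter microstructure surrogate). Passing tests therefore demonstrate
that the algorithms recover structure of the planted kind at the stated
sizes — not that real microarray or imaging-genetics data meet these
assumptions.

Parameter defaults define the study conditions. `n_samples_per_cell = 12`
was fixed a priori by a power calculation: a two-sample t-test with 12
replicates per arm detects a 1.5 log2-unit shift (marginal SD ≈ 0.9 under
the default Ω) with >90% power at the p ≈ 0.015 thresholds BH induces at a
10% FDR with ~16% true signals. `cluster_effect` defaults to 1.0; the
recovery benchmarks use 1.5, the effect size at which the labeling rule is
designed to operate. The interactome background is deliberately sparse and
motif-free (max degree 3) so that the planted star and biclique are the
only coherent modules; a denser background would plant accidental modules
and make "exactly two SPNs" ill-posed. The causal and eQTL SNPs are planted
at loci where their group comparisons are testable (≥3 carriers and
non-carriers; ≥5 homozygous-minor subjects), so a failure to detect them is
a property of the method, never of an empty contrast. All randomness flows
from one seed through named per-stage streams, giving byte-identical
reruns and stage-level reproducibility.

## Response clustering

For each time point the per-gene mean difference d_g (treated −
control) is standardized **across genes**: z_g = (d_g − mean(d)) / sd(d).
The Z-score is thus a cross-gene scale, on which the ±1 thresholds mean
"one SD more responsive than the typical gene at this time point". This was
a genuinely open choice; alternatives (per-gene standardization across
replicates) would make z a t-statistic and blur the distinction from the
Welch test that is applied alongside. Labels require all three conditions
conjunctively: |z| beyond its threshold, Welch p < `alpha` (0.05), and BH
q ≤ `fdr` (0.10). Applying the nominal and the FDR thresholds jointly is
deliberate: the nominal filter protects against the adaptivity of the BH
cutoff when many genes respond.

The three responses (treatment, development, interaction) come from a
per-gene two-way fixed-effects ANOVA fitted by least squares. All genes
share one model matrix, so the package fits a single multi-response linear
model and decomposes sums of squares from the QR effects; on the balanced
design the sequential and marginal tests coincide (verified against
per-gene `anova(lm(...))` in the tests). Zero-variance genes are reported
with p = 1 rather than dropped. Genes feeding each network are those with
BH q ≤ 0.05 in that response, capped at the 500 largest F statistics — a
cap that keeps the graphical model well-posed, since no selection rule is
dictated by the biology here.

## Graphical Gaussian models with local-fdr edge selection

The correlation matrix is shrunk toward the identity,
R* = λI + (1 − λ)R, with the analytic variance-minimizing intensity
λ = Σ var̂(r_ij) / Σ r_ij² clipped to [0, 1] (the standard shrinkage
estimator with the identity target; it guarantees positive definiteness
when genes outnumber samples). Partial correlations come from the full
inverse, p_ij = −ω_ij/√(ω_ii ω_jj), jointly and symmetrically — not from
nodewise regressions.

Edge selection fits the two-component mixture
f(r) = η₀ f₀(r; κ) + (1 − η₀) f_A(r), where
f₀(r; κ) = (1 − r²)^((κ−3)/2) / B(1/2, (κ−1)/2) is the null density of a
correlation with κ effective degrees of freedom. Numerical choices:

* κ is fit by **censored** maximum likelihood: values with |r| above the
  0.75 quantile contribute only their null tail probability, which makes
  the fit robust to the alternative component concentrated at large |r|;
  the optimization is one-dimensional in log(κ − 3) over (3, 10⁷).
* η₀ is the censored-ML ratio mean(|r| ≤ r₀) / P₀(|R| ≤ r₀; κ̂), capped at
  1. (The terminal slope of the Grenander estimator, the other standard
  choice, is degenerate at the right boundary and was rejected.)
* the mixture density is estimated through the Grenander (least concave
  majorant) density of the null p-values, so
  lfdr(r) = η₀ / ĝ(p(r)) is monotone non-increasing in |r| by
  construction and capped at 1.

The default edge threshold, local fdr ≤ 10⁻¹³, is the stringent full-study
setting; designs of a few hundred samples cannot reach it, so the pipeline
and examples use 10⁻² (exposed as `threshold`). On null-only data (50 genes
× 40 samples) the acceptance checks require η̂₀ ≥ 0.95 and an empty network
at 10⁻² in ≥95% of runs.

Two statistical floors are worth recording. First, the planted-edge
recovery benchmark runs at 50 genes and 40 replicates per design cell
(320 arrays); with 40 *total* samples the planted partial correlations
(at most 0.267 under the diagonal-dominance construction
ω_ii = 1 + Σ|ω_ij| + 0.1) are information-theoretically undetectable at
AUC 0.9. Second, consistency of the estimator is asserted through the mean
absolute error and a 3.5/√n per-entry band at n = 5000, because the maximum
over 45 entries has a ~2.5/√n sampling floor that no unbiased estimator
beats.

## Topology

`topology_summary()` reports size, degree summaries, the average local
clustering coefficient (degree-<2 nodes contribute 0), the mean shortest
path on the largest component, the small-world index
σ = (C/C_rand)/(L/L_rand) against Erdős–Rényi G(n, m) references with the
same node and edge counts (degree-preserving rewiring is reserved for the
permutation test, where it matters), the power-law exponent via the
continuous-approximation MLE γ̂ = 1 + n / Σ ln(k_i/(k_min − ½)) at fixed
k_min, and the hiveplot degree bands (<30, 30–80, >80). The continuous
approximation is biased at k_min = 1 (a known property); exponent recovery
is therefore validated in the k ≥ 5 tail, and the estimate is reported as a
qualitative summary, not an inferential quantity. The degenerate case
"all degrees equal k_min" is rejected: it carries no tail information.

## Power graphs and super-power nodes

The decomposition is *strict*: every base edge is abstracted by exactly one
power edge, so `expand_power_graph()` is the exact inverse of
`decompose_power_graph()` (the published power-graph tooling permits
hierarchy-mediated sharing; strictness costs a little compression and buys
testable losslessness, which is what module detection needs). Candidate
power nodes are the dendrogram cut-sets of average-linkage clustering under
Jaccard similarity of neighborhoods — run once on open neighborhoods N(v)
(which exposes biclique sides and star leaf sets) and once on closed
neighborhoods N(v) ∪ {v} (which exposes cliques). The greedy cover accepts
the candidate pair (disjoint sets, a set with a common neighbor, or a set
with itself) abstracting the most currently-uncovered edges (minimum 2),
with ties broken by smaller combined size and then the lexicographically
smallest member set, and enforces laminarity (any two accepted power nodes
nested or disjoint). Leftover edges become singleton–singleton power edges.
Everything is deterministic: reruns are bit-identical.

An SPN is a connected component of the meta-graph whose vertices are the
power nodes of size ≥ 2 plus the singletons attached to them by power
edges. Two filters are exposed: `min_power_nodes` (default 2 — a single
power node is just a cluster, not a connected set of them) and
`min_proteins` (default 5). The protein floor separates the *main* modules
from the two-edge star fragments any sparse background contains; it is a
declared convention — with the sparse default background it cleanly admits
the planted star (11 proteins) and biclique (12) while excluding chance
fragments (≤4). The hub of an SPN is its member of maximal base-graph
degree, ties broken lexicographically.

## Connectivity, enrichment and genetics

The degree-matched permutation test replaces each query protein by one
drawn (without replacement within a draw) from its log₂ degree bin,
widening undersized bins outward with a warning. Both statistics — direct
edge count and mean direct degree — use the add-one estimator
p = (1 + #{null ≥ obs})/(1 + n_perm), which can never return 0. With an
integer statistic on a sparse background the reported p is discrete and
conservative (it has atoms, including one at 1); calibration is therefore
checked on the randomized tie-broken transform, which is exactly uniform
for an exchangeable statistic — the reported p itself keeps the
conservative formula.

Enrichment uses the exact hypergeometric upper tail (one-sided, matching
"enrichment") with BH across categories; the universe defaults to the
annotation-collection union plus the query, and is exposed, because no
single universe is canonical. The multi-set overlap test is exact for two
sets and Monte-Carlo (resampling each set at its observed size) for three
or more. Disorder-promoting residues are fixed to the consensus set
{A, R, G, Q, S, P, E, K}.

Genotype QC removes SNPs with MAF < 5% or call rate < 99%. MAF is folded
to ≤ 0.5 with the allele flip recorded. Association uses OLS on
minor-allele presence (dominant coding, the primary contrast) or allele
count; missing genotypes are dropped pairwise. The SNP-set test is
self-contained: the statistic Σ −log₁₀ p over the set's additive-coding
single-SNP tests is compared with its distribution under phenotype
permutation (default 1000 permutations), leaving the genotype correlation
structure intact; the competitive "matched random SNP sets" null is out of
scope. Internally the per-SNP p-values use the correlation-t identity
(verified against `lm()` in the tests) so that a 1000-permutation run is a
single matrix product. The cis-eQTL contrast is homozygous-minor versus
the rest, by pooled-variance t-test; covariate adjustment is available in
`snp_association()` but off by default, since the primary contrast is
reported unadjusted with covariate balance checked separately
(`group_covariate_tests()`).

## Problem sizes and limitations

The validation suite runs at desk scale, chosen so the full suite and the
acceptance script each finish in a few minutes on one CPU: 50–200 genes,
12–40 replicates per cell, interactomes of ~220 proteins, 100-seed
recovery sweeps, 200–500 simulation calibration loops, and 1000-permutation
tests. Known limitations: the greedy power-graph cover is not the minimal
power graph (minimality is NP-hard) and its compression depends on the
clustering-derived candidate family; the local-fdr machinery assumes a
unimodal null around 0 and ≥100 gene pairs; σ is undefined for graphs whose
largest component has fewer than 10 nodes; and none of the genetics
handles linkage disequilibrium, imputation or population structure.
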