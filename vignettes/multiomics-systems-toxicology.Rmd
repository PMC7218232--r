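---
title: "Methods: five-modality systems-toxicology integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: five-modality systems-toxicology integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`toxomix` implements, as one tested pipeline, the statistical core of a
multi-omics inhalation toxicology analysis: five molecular layers (mRNA,
miRNA, protein, metabolite, lipid) measured on mouse lungs across six
exposure arms (filtered air; reference cigarette smoke; two heated-tobacco
aerosols; cessation; switch) and three dissection time points. The pipeline
runs on synthetic studies produced by its own generator, which emulates the
design and the statistical structure such an experiment produces; the real
instrument-level data processing (microarray normalisation, peptide
quantification, lipid identification) is out of scope and assumed done.

# The synthetic study generator

Each modality is generated on its log2 model scale as
`Y = intercept + W Z' + noise`, where the score matrix `Z` holds three
planted factors per sample:

* **Factor 1 (exposure).** Mean score 3 in the smoke arm at every time
  point; 0 in the air and heated-tobacco arms; cessation and switch decay
  from 50% of the smoke score at 3 months to 25% at 6 months (4 months is
  interpolated linearly in time, 41.7%). Within-cell standard deviation
  0.5. Loadings are nonzero for a modality-specific fraction of features
  (mRNA/protein 0.25, metabolite/lipid 0.4, miRNA 0.15) with scale 0.6.
* **Factors 2 and 3.** Sample-level nuisance factors loading only on the
  metabolite and lipid layers respectively — the structure an integration
  method must separate from the shared exposure response.

Protein features map one-to-one onto the first 500 genes; their factor-1
loadings correlate with the matched mRNA loadings at `rho = 0.72`. This
value was calibrated once so that the gene-matched mRNA/protein log2
fold-change coefficient of determination averages ~0.38 over seeds (the
band real lung data shows, roughly 0.35--0.42); a 20-seed calibration test
keeps the mean inside [0.30, 0.47].

Missingness has three layers: by design, proteomics measures 8 of the 9
animals per cell and metabolomics skips the 4-month time point entirely;
on top of that, random sample/modality dropout (rate 0.02) emulates QC
exclusions; and within measured metabolomics samples, values below the 8th
abundance percentile of each metabolite are censored to missing, emulating
detection-limit missingness (the kind that minimum-imputation is meant
for). Design-level missing samples are never imputed. The BALF total
immune-cell covariate is an affine function of the factor-1 score
(intercept 50, slope 40, noise sd 8, truncated at zero, thousands of
cells).

Default feature counts (2000/500/200/150/100) are a desk-scale reduction
of a realistic study (~17,500 mRNAs, 5,000 proteins, 670 metabolites, 400
lipids, 360 miRNAs); all dimensions are configurable. What the generator
does *not* emulate: feature-feature correlation beyond the planted
factors, batch structure, heavy-tailed noise, and compositionality of the
lipidome — so green tests certify the machinery, not performance on real
data.

# Differential abundance

Lipid concentrations are divided by the sample's total protein (mg);
metabolite censored values are imputed as the per-metabolite observed
minimum; both layers are then log2-transformed. Each exposure arm is
compared with the Sham arm at the same time point by a two-group
equal-variance linear model per feature. Feature variances are shrunk by
empirical Bayes: the prior degrees of freedom `d0` and variance `s0^2`
are obtained by moment matching on log variances (trigamma inversion by
Newton iteration, tolerance 1e-8, at most 50 steps; exactly constant
variances return `d0 = Inf` with the common value). The moderated t uses
the posterior variance `(d0 s0^2 + d s^2) / (d0 + d)` with `d0 + d`
degrees of freedom; at `d0 = 0` it is exactly the ordinary pooled t.
P-values are two-sided and BH-adjusted within each (modality, contrast)
family; the significance threshold is FDR < 0.05. Features missing in
more than half of either arm are excluded; remaining missingness is
handled pairwise-complete per feature.

# Causal-network perturbation

A signed backbone network with disjoint signed downstream gene sets
translates transcript fold changes into backbone differential values
`f_i = mean(s_ig * logFC_g)` over measured downstream genes. The
perturbation amplitude is the quadratic form

    NPA = mean over edges of w_ij (f_i - s_ij f_j)^2  +  mean over nodes of f_i^2

— a deliberate, documented simplification: a node-energy term plus a
penalty for differential values that disagree with the signed topology.
Three companion statistics guard it:

* `p_O` (downstream permutation, upper tail): are the amplitudes larger
  than when genes are randomly reassigned to downstream sets?
* `p_K` (topology permutation, lower tail): because the quadratic form
  penalises sign disagreement, a perturbation *consistent* with the
  backbone makes the observed amplitude **smaller** than under
  degree-preserving edge rewiring; `p_K` is therefore the probability that
  a rewired backbone scores at or below the observed one. Under fold
  changes with no relation to the network both statistics are uniform.
* `p_replicates`: animals are bootstrapped within arms and the amplitude
  recomputed; the statistic is the bootstrap probability of falling at or
  below the mean of the downstream-permutation null (the permutation bias
  level). The 95% CI is the bootstrap percentile interval.

Amplitudes significant in all companions are aggregated: within each
network they are normalised by that network's maximum across contrasts,
summed over networks with equal weight (BIF), and rescaled so the most
perturbed contrast reads 100 (RBIF). Non-significant amplitudes contribute
zero — one possible convention, flagged as a choice rather than inherited.

# Latent factor integration

The integration model is Gaussian group factor analysis fitted by
variational EM: `Y_m = W_m Z' + eps_m`, standard-normal prior on scores,
and an automatic relevance determination (ARD) prior with per-(modality,
factor) precision on weights, so factors switch off per modality. Noise
and ARD precisions are point-maximised each iteration, which keeps the
evidence lower bound (ELBO) non-decreasing; the trajectory is stored and
asserted in tests. Missing sample/modality blocks simply drop out of the
sums — no imputation enters the factor model.

Defaults: each modality centered per feature and scaled to equal total
variance (so no layer dominates — the scaling question is genuinely open;
we scale); `k_init = 10`; relative ELBO tolerance 1e-6; at most 300
iterations; initialisation from the singular vectors of the stacked data
(deterministic; the seed only fills rank-deficient directions). At
convergence, factors are retired if their *incremental* (sequential
residual) variance explained is below 0.1% in every modality — incremental
rather than marginal, because exactly low-rank data can split one
direction across several factors that ARD alone does not merge;
numerically collinear score vectors (|r| > 0.999) are first absorbed into
their partner. Reported variance-explained tables are the usual marginal
per-factor `R^2` per modality. Factor signs are fixed by making the
largest-magnitude weight positive; sign is otherwise meaningless and tests
compare scores to planted truth up to sign.

The cross-check is a sparse generalized canonical correlation (block
sparse PLS, canonical mode, fully connected design): alternating updates
`a_m ∝ X_m' Σ_{m'≠m} X_{m'} a_{m'}` hard-thresholded to the `keep = 30`
largest absolute entries (ties by feature index) and renormalised, with
canonical-mode deflation of each block by its own score. It requires
complete cases across modalities; dropped samples are reported.

# Association network

Interaction records are filtered with the standard source-specific rules
(gene-gene links kept at combined score > 0.7, strictly; miRNA links need
at least two publications and two non-high-throughput methods;
metabolite-gene links kept unconditionally) and weighted 0.1
(metabolite-gene, miRNA-gene) or `(1 - score) + 0.1` (gene-gene).
Self-loops are removed, parallel edges collapse to the minimum cost (our
choice), and mRNA/protein features of one gene share a single gene node
(an assumption the display conventions of such analyses suggest).

Terminals for the exposure factor: per modality, absolute weights are
normalised by the modality maximum; the chance expectation is the mean
normalised weight; features at or more than twice the expectation survive,
capped at the 200 largest prizes. Both the normalisation and the chance
null are our formalisations of an underdocumented step and are
configurable. When a gene node receives prizes from both its mRNA and its
protein feature, the larger prize wins.

The prize-collecting Steiner forest minimises

    sum(edge costs) + mu * sum(node degrees) + omega * #trees - beta * sum(prizes)

with hub penalty `mu = 0.0005` (degree in the full network), tree cost
`omega = 0.6`, prize scale `beta = 1000`. Instances with at most 12 nodes
are solved exactly by subset enumeration (for a fixed node set the optimal
forest is the induced minimum spanning forest with edges >= omega
removed). Larger instances use Goemans-Williamson moat growth on a
virtual-root transformation (root connected to every node at cost omega;
`max(0, beta*prize - mu*deg)` drives growth), followed by an induced-MSF
rebuild, optimal-subtree (strong) pruning via a rerooting dynamic program,
and — on instances up to 400 nodes — a single-node add/remove local search.
On 50 random 6--12-node instances the heuristic matches the exhaustive
optimum in at least 90% of cases and is never more than 5% off; that
property is a standing test.

The grid search (`omega` 0.2--1, `beta` 100--2000, `mu` fixed) records
terminal coverage and tree counts; "saturation of percent covered" is
formalised as the smallest `beta` whose coverage is within 2 percentage
points of every larger `beta`, among `omega` values whose tree count falls
in a configurable band (default 3--30). At the synthetic scale coverage
saturates at 100% from the smallest prize scale — with normalised prizes
in (0, 1] and `beta >= 100`, every terminal is worth opening as its own
tree — so the curve is mainly a diagnostic of tree structure here. The
final network is the union of 10 solver runs with multiplicative uniform
noise (`r = 0.1`) on edge costs, annotated with selection frequencies,
then clustered by Girvan-Newman edge betweenness (costs as distances) cut
at maximum modularity. Cluster profiles report, per cluster and contrast,
the mean log2 fold change and percent significant molecules, one
contribution per modality.

# Enrichment

Preranked gene-set enrichment uses the weighted Kolmogorov-Smirnov running
sum with weight exponent 1 on the signed factor weight vector (mRNA and
protein analysed separately; whether the original ranking used signed or
absolute weights is not documented — signed is chosen because it
distinguishes induction from repression). The null is gene-label
permutation at preserved set size — simpler than adaptive multilevel
splitting and adequate up to ~1e5 permutations; the smallest attainable
p is `1/(n_perm+1)`. The normalised score divides by the mean absolute
null score of matching sign. Overrepresentation uses the one-sided
hypergeometric tail with BH adjustment. Set sizes default to [10, 500]
after intersection with the universe.

# Determinism and problem sizes

One global seed is expanded into named per-stage substreams
(`stage_seed`), so re-running or inserting a stage never perturbs the
others; two runs from the same configuration produce byte-identical
tables, which the manifest (MD5 per output file) asserts. The shipped
analysis and the test suite run at the desk scale above: the full
pipeline completes in about a minute on one core; the test suite exercises
oracle comparisons (exhaustive Steiner solver, hypergeometric closed form,
brute-force permutation GSEA at 1e4 permutations on a 200-gene universe,
direct step-up BH, prior-df recovery at 5000 features over 20 seeds) in a
few minutes.

# Known limitations

* The perturbation amplitude is a formalisation, not a port of any existing
  multi-network scoring suite; only its qualitative behaviour (ordering
  of exposure arms, permutation calibration) should be interpreted.
* The factor model is Gaussian-only; count-like or compositional layers
  would need transformation upstream.
* sGCCA discards incomplete samples (70 of 162 at the default design),
  exactly as canonical-mode block PLS requires; it is a cross-check, not
  the primary integration.
* Edge-betweenness clustering recomputes betweenness after every removal
  and scales poorly beyond a few thousand edges; the ensemble union
  networks here are far below that.
* With normalised prizes and the default prize scale every terminal is
  individually profitable, so terminal coverage is not a discriminating
  model-selection signal at this scale; tree count carries the structure.
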