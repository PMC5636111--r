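---
title: "Perturbance-weighted disease-network discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbance-weighted disease-network discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`pertnet` searches a directed gene–gene interactome for the connected
module that best explains a binary case/control contrast measured on
continuous per-gene scores, and then fits that module as a linear structural
equation model (SEM). This vignette documents the statistical models, the
tunable parameters, the synthetic world used for validation, and the design
decisions taken where more than one convention was defensible. It states no
empirical result that the package's tests do not themselves compute.

## Gene scores from genotypes (supervised PCA)

Genotypes are additive-coded (0 frequent homozygote, 1 heterozygote, 2 rare
homozygote). SNPs are assigned to a gene when they fall within the gene
locus ± 5000 bp (`flank`, 1-based inclusive coordinates). Within a gene,
each SNP is scored by a pooled-variance two-sample t of dosage against the
outcome, a subset is retained, and the first principal component of the
mean-imputed, centred retained dosages becomes the gene score.

Choices that were genuinely open:

* **Selection rule.** Supervised PCA leaves the supervision threshold
  open. The default retains SNPs with |t| at or above the
  gene-wise median (`spca_config(selection = "median")`); a global
  top-fraction and an absolute threshold are available. The inclusive
  median (≥, not >) keeps single-SNP genes alive, for which PC1 is just the
  centred dosage.
* **Missing dosages** are mean-imputed per SNP before centring — the
  simplest convention consistent with additive coding.
* **Sign.** PC1 is sign-indeterminate; it is oriented so its point-biserial
  correlation with the outcome is non-negative (cases tend to score
  higher). Flipping all dosages (2 − g) leaves |cor(PC1, C)| unchanged.

## Edge perturbance

For an arc *j → k* the recursive trivariate Gaussian model
`X_j = a·C + e1`, `Y_k = b·C + c·X_j + e2` is fitted by per-equation least
squares, which is exact ML for this system. The tested quantity is the
total group effect on the child through the parent, `tau = b + a·c`, with a
first-order delta-method standard error assembled from the two equations'
coefficient covariances (the cross-equation blocks vanish because the
likelihood factorises). The reference is Student t with n − 3 df — three
estimated mean-structure parameters.

The one-parameter `tau` test is the default because perturbance is defined
as one combined quantity — the total group difference transmitted through
the link; a 2-df likelihood-ratio test of any group effect
(`method = "lrt"`) is available but is *not* what the weight calibration
below assumes.

The weight is `w = 1/(−ln p)` with the natural logarithm, which is what
makes p < 0.05 correspond to w < 0.33 (1/−ln 0.05 = 0.3338), the
"perturbed" threshold used throughout. p is
clamped to [1e−16, 1 − 1e−16] so w stays finite and strictly increasing in
p. Under the null the test's empirical size is 5% (checked by a 2000-edge
Monte-Carlo calibration in the acceptance suite); swapping group labels
flips the sign of tau but not p or w.

## Steiner tree

Shortest paths follow arc directions and minimise Σw, so the most perturbed
routes are the shortest. Each terminal-pair path gets a Fisher combination
of its edge p-values, χ² = −2Σ ln pᵢ on 2m df, and survives only if its
upper-tail probability beats α divided by the number of finite-distance
ordered terminal pairs (the Bonferroni denominator is the number of
*paths* tested, not edges — the test is applied to paths).

The tree is Kou's construction restricted to surviving paths: metric
closure on the terminals, MST, expansion to concrete directed paths, second
MST, iterative pruning of non-terminal leaves. Conventions:

* The MST steps run on symmetrised distances (min of the two directions)
  because spanning trees are undirected objects; the final edges keep their
  original directions, from which roles are read off (source = in-degree 0,
  target = out-degree 0, connector = both positive).
* When both directions of a terminal pair are significant, the cheaper
  enters the closure.
* All tie-breaks are lexicographic on node identifiers (a hand-rolled
  Dijkstra guarantees this), so identical inputs give identical trees.
* A disconnected closure yields a spanning forest with a warning and a
  `main_component` flag, rather than an error: partial connectivity is a
  finding, not a failure.
* Path filtering happens at closure construction (before the first MST);
  filtering after the first MST would also be coherent, but doing it at
  the closure makes the admitted path set monotone in α.

The heuristic carries Kou's 2× optimality guarantee; the acceptance suite
checks it against an exact Steiner oracle that enumerates Steiner-node
subsets on fixtures of up to 12 nodes.

## SEM over the tree

Every gene becomes a variable with equation
`Y_j = β_jC·C + Σ_{k∈pa(j)} β_jk·Y_k + U_j`; the group node C feeds every
gene. Disturbance covariances ψ_jk are admitted only for sibling pairs:
out-degree-0 (target) genes not joined by a directed edge — the bow-free
condition, which keeps the model identified. Fitting minimises
`F_ML = log|Σ(θ)| + tr(S Σ⁻¹) − log|S| − (p+1)` over the joint vector
(C, Y), with Σ(θ) = (I − B)⁻¹ Ψ (I − B)⁻ᵀ and var(C) fixed at its sample
value. LRT = n·F_ML at the optimum; AIC = −2logL + 2t; SRMR is the root
mean square of standardised covariance residuals *including the diagonal*
(mean residuals are not modelled: the model is covariance-only, with C
entering as an observed regressor rather than through multi-group means).

Constraint variants (`sem_variants()` lists the seven standard ones):

* **β mode.** `ade` fixes each β_jk at the Average Direct Effect —
  within-group OLS slopes of child on parent, weighted by group
  frequencies Σ_g (n_g/n)·slope_g. `two` estimates one shared coefficient
  for arcs with non-negative pooled endpoint correlation and one for the
  rest (a two-parameter scheme needs an edge partition, and the sign of
  the endpoint correlation is the natural one). `fixed` uses ±0.1
  constants on the same
  partition; `free` estimates every arc.
* **Variances** equal (one ψ) or unequal (one per gene); **covariances**
  zero or bow-free.

Free-β / unequal-variance / zero-covariance models are solved in closed
form (per-equation OLS is exact ML for recursive Gaussian systems — the
acceptance suite checks agreement to 1e−6); every other combination runs
BFGS from an OLS warm start with log-parameterised variances, a 1e−8 ridge
on a numerically singular S, and a non-convergence diagnostic reporting the
gradient ∞-norm. Model degrees of freedom count the p(p+1)/2 gene moments
plus the p C–gene covariances, minus t free parameters (var(C) is fixed and
not counted on either side).

Selection is minimum AIC among converged fits, ties broken by smaller t,
with SRMR < 0.05 as an acceptability *flag* — an unacceptable minimum-AIC
model is still returned, flagged.

Bootstrap significance resamples cases and controls separately (stratified,
preserving the case/control ratio), refits, and uses t = MLE / bootstrap SE
with a two-sided normal reference; a gene is "perturbed" when its β_jC has
p < 0.05. The ADE values are data-derived and therefore recomputed inside
every resample.

## Latent-variable extension

Target pairs (out-degree-0 genes, never joined by a directed path) are
screened on the *residual* correlation of their fitted disturbances — the
association left over after removing modelled parent and C effects — rather
than the raw score correlation, because the screen exists to repair model
misfit; a raw correlation would re-detect signal the tree already explains.
Fisher's normalising transform gives t = atanh(r)·√(n−3), and |t| > 2
(≈ 4.6% two-sided under the null) selects a pair.

Each selected pair gets the model `LV = γ·C + d`, `Y_j = LV + e_j`,
`Y_k = λ·LV + e_k`: the first loading is fixed to 1 for identification —
the minimal standard convention — and C→LV is free. With 6 saturated moments and 5 free parameters the LRT against the
saturated covariance has 1 df; good fit means p ≥ 0.05, and a pair is
"perturbed" when additionally the bootstrap p of γ is < 0.05. Residual
variances are log-parameterised, so Heywood cases terminate on the boundary
and are flagged rather than producing negative variances.

All selected pairs enter the augmented network (the good-fit subset is a
flag, not a filter), one LV node and two links per pair, leaving the tree's
own nodes and edges untouched: node count = tree + pairs, edge count =
tree + 2·pairs.

## Topology and enrichment

Weighted betweenness uses directed shortest paths on w (most perturbed =
shortest), counting multiple shortest paths fractionally. "Upper quartile"
is read strictly (> the 75th percentile, ties excluded), so a network with
all-equal centralities has an *empty* essential set — the conservative
boundary convention. Hubs are connectors with total degree > 3; springs and
sinks compare source out-degrees and target in-degrees against their own
role-wise quartiles; secondary sources are direct targets of sources with
in-degree 1 and out-degree 1.

The seed-connectivity test compares the seeds' median degree and mean
directed shortest-path distance (hop distances; unreachable ordered pairs
are excluded rather than set to ∞, and the excluded count is reported)
against B random node sets or node
permutations, with the +1-corrected empirical p-value
(1 + #{null ≥ obs})/(B + 1), which is consistent with reporting p < 0.001
at B = 1000.

Enrichment is an upper-tail hypergeometric test per gene set with
Bonferroni correction over the sets that can overlap the universe (K ≥ 1).
The default universe is the mapped interactome's genes, not the genome —
the module was drawn from the interactome, so a genome universe would
manufacture enrichment. Results sort by gene ratio k/n, the dot-plot order.

## The synthetic world

`simulation_spec()` defines the stated world of all validation
experiments: a 30-node interactome whose unordered pairs connect with
probability 0.1, one third of connections bidirected (the proportion seen
in curated signalling networks, where roughly a third of merged-pathway
edges are bidirected), 300 samples per group, and a planted 5-gene
perturbation route with a = 0.8 on the head, path coefficients c = 0.5 and
a direct group effect b = 0.4 on every downstream route gene. The b value
deserves a note: with b = 0 the group effect would decay geometrically
along the route (0.8, 0.4, 0.2, 0.1) and the downstream arcs would carry no
detectable perturbance — the planted path would not be a perturbation
route at all. Setting b = 0.4 encodes the intended biology: every route
gene carries disease-associated variants of its own, on top of the signal
propagated from its parent.

Two further generator semantics keep the planted truth well defined. The
route is an *induced* path (generated shortcuts among route genes are
dropped), since a shortcut between two group-shifted genes would itself be
a genuinely perturbed connection and the "true" edge set would be
ambiguous. And the seed set emulates what a GWAS on this world would
return: every gene with a true marginal group effect (all route genes and
both latent-pair genes) plus random extras standing in for false or
unmappable associations. Latent pairs share a factor LV = γ·C + f
(γ = 0.6, loadings 1 and 0.8) and are placed on non-route genes.

What the generator does *not* emulate — and hence what a green test does
not establish: linkage-disequilibrium structure in genotypes, non-Gaussian
score distributions, hub-dominated degree distributions, measurement error
in the interactome, or confounding between ancestry and outcome. The
synthetic genotypes draw dosages binomially with group-specific allele
frequencies and independent SNPs.

All generator randomness flows from one spec-level seed through
per-operation streams (seed·1000 + counter), so every artifact is
bit-reproducible.

## Numerical conventions

* p-values clamped to [1e−16, 1 − 1e−16] before the w transform; caps are
  what keeps w finite on overwhelming evidence.
* BFGS convergence at relative tolerance 1e−12, max 500 iterations; a
  non-PD implied or disturbance covariance returns a large penalty value
  instead of an error inside the line search.
* Degenerate inputs: constant genes give p = 1 (uninformative edge,
  flagged); arcs with endpoints missing from the scores are dropped and
  counted, with an abort past 50%; a singular sample covariance gets a
  logged 1e−8 ridge.
* All stochastic stages (bootstrap, LV fits, connectivity tests, the
  generator) take explicit integer seeds, and the pipeline driver records
  every seed and threshold in its JSON manifest together with md5 checksums
  of all artifacts.

## Known limitations

* The SPH tree is a heuristic: only the 2× bound is guaranteed, and on
  dense graphs with many equally perturbed alternatives the recovered tree
  can legitimately bypass a specific planted arc (its signal then tends to
  reappear in the covariance screen, as the worked example in the README
  shows).
* The SEM assumes joint Gaussian scores and a recursive (acyclic) directed
  part; ordinal or heavily skewed scores are outside the model family.
* Bow-free covariances are screened and fitted pairwise; a joint model of
  all selected covariances, or LVs loading on more than two genes, is out
  of scope.
* The bootstrap refits the full model per resample; for large trees with
  many bow-free pairs this is the dominant cost, and B below 1000 trades
  SE precision for time (the package warns below 100).
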