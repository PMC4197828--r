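---
title: "Methods: from two-colour intensities to co-expression clusters, cis-elements and hubs"
author: "coexpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-colour intensities to co-expression clusters, cis-elements and hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpipe)
```

coexpipe chains the statistical steps of a flg22 / MAPK-mutant style
transcriptome analysis: moderated differential expression on dye-swapped
two-colour arrays, model-based co-expression clustering with a
misclassification-controlled assignment rule, positional cis-element
enrichment, GO and kinetic-class enrichment, and interaction-network hub
calls. This vignette explains each model, its assumptions, the tunable
parameters and their defaults, and the choices made where the underlying
methods literature leaves the details open. Every quantitative statement
here is recomputed by the test suite or by `scripts/acceptance.R`; none are
copied from elsewhere.

## The data model and the simulator

A two-colour hybridisation measures, per probe, a red and a green intensity.
The analysis works on `M = log2(R/G)` and `A = (log2 R + log2 G)/2`. The
experimental design (`array_design()`) is a set of labelled contrasts
(default 7: wild type + elicitor vs. wild type, three mutants vs. wild type,
and each mutant + elicitor vs. the untreated mutant), with 3 biological
replicates, one dye-reversed technical replicate each, and 2 duplicate
probes per gene (one per strand).

`gen_two_colour_arrays()` emulates exactly the structure the downstream
statistics assume:

* the raw `M` of each measurement is `±(true log-ratio) + b(A) + noise`,
  where the sign is negative on dye-reversed arrays, `b` is a configurable
  intensity-dependent dye-bias curve (default zero), and `A` is uniform on
  6–16 (CATMA-style intensity distributions are not published, so the range
  is an explicit, configurable stand-in);
* per-gene residual variances follow a scaled inverse chi-square prior
  `sigma_g^2 ~ d0 s0^2 / chisq(d0)` with defaults `d0 = 4`,
  `s0^2 = 0.05` — the hierarchical model under the moderated t-statistic —
  and measurement noise is scaled so that the *replicate-level averaged*
  log-ratio has variance `sigma_g^2`, which makes prior-recovery tests
  exact;
* each differentially expressed gene (a `de_fraction` of all genes) receives
  a ±`effect_size` log2 effect in a random non-empty subset of contrasts.

What the simulator does *not* model: scanner images, spatial artefacts,
probe cross-hybridisation, correlated probe effects, or non-Gaussian heavy
tails. Passing tests therefore demonstrate the statistical machinery under
its own assumptions — calibration and recovery claims on real arrays rest on
how well those assumptions hold there.

## Normalisation, averaging, moderated tests

`loess_normalize()` removes the intensity-dependent dye bias by local linear
regression of `M` on `A` (tricube weights, span 0.3, two robustness
iterations; both configurable). The span follows common two-colour practice.
A hybridisation with numerically constant `A` degenerates to mean-centring.

`average_replicates()` first flips dye-reversed arrays back to biological
orientation, then averages over duplicate probes and the dye pair within
each biological replicate, so each gene keeps exactly one value per
biological replicate per contrast — the replicate-level matrix feeds the
variance estimate, and its mean over replicates is the log-ratio matrix that
everything downstream consumes.

`estimate_prior()` fits `(d0, s0^2)` by moment matching on `log s_g^2`
against the scaled-F law, delegating to limma's `fitFDist`; all-equal
variances yield `d0 = Inf`. `moderated_test()` then uses the posterior
variance `s̃_g^2 = (d0 s0^2 + d_g s_g^2)/(d0 + d_g)` and the statistic
`mean / (s̃_g sqrt(1/n_rep))`. The default reference distribution is the
standard normal — appropriate when the data show no evidence of
between-gene variance heterogeneity, as in the design this pipeline
emulates — with a t reference on `d0 + d_g` degrees of freedom available by
flag. The normal reference is anticonservative when `d0` is small; the test
suite asserts exactly this direction.

Three adjustment methods are available: Bonferroni, Benjamini–Hochberg, and
a semi-parametric local false discovery rate (two-component mixture on
probit-transformed p-values, Gaussian kernel density for the marginal, null
proportion bounded by the density ratio on the null-dominated side). The
local fdr is this package's own fully-specified estimator of the posterior
null probability; BH is the default for the DE call because it is the most
reproducible of the three. The DE threshold is adjusted p ≤ 0.05.

The *MAPK-dependence* rule (`mapk_dependence()`) declares a wild-type
flg22-regulated gene *affected* in a mutant when the mutant and wild-type
flg22 log-ratios differ by ≥ 1 log2 unit — a two-fold loss (or gain) of
response. The rule is sign-agnostic and applied only to genes DE in the
wild-type contrast.

## Constrained Gaussian-mixture clustering

Genes that pass Bonferroni < 0.05 in at least one contrast are clustered on
their 7-dimensional mean log-ratio profiles under the mixture
`sum_k pi_k N(mu_k, lambda_k C)` with `det(C) = 1`: components share
orientation and shape but differ in volume. This family regularises the
full-free-covariance mixture (d = 7 would cost 28 parameters per component)
while still letting tight and diffuse clusters coexist.

`fit_vee_em()` implements EM for this family. The M-step has no closed form;
it is solved by inner alternation: with weighted scatter matrices `W_k`,
`lambda_k <- tr(C^-1 W_k)/(n_k d)` and `C <- sum_k W_k / lambda_k` rescaled
to unit determinant, iterated to a 1e-8 relative tolerance. Numerical
choices: k-means++ seeding with the short-run strategy against local optima
(10 restarts by default, each run for 25 iterations, only the best
continued to convergence), convergence at relative log-likelihood change
< 1e-8 or 500 iterations, a volume floor of 1e-8, and one reseeding attempt
for a collapsing component before a start is abandoned. `K = 1` is solved in closed form. Log-likelihood monotonicity,
the determinant constraint and posterior row-stochasticity are asserted by
property tests, and the fit is cross-checked against the independent
implementation in mclust (model "VEE").

`select_K()` minimises `BIC = -2 loglik + m log n` with
`m = (K-1) + Kd + K + (d(d+1)/2 - 1)` over K = 2–40 by default.

### Misclassification-controlled assignment

A maximum-a-posteriori label is only useful if it is probably right.
`threshold_map_assign()` classifies observation *i* only when its maximal
posterior probability exceeds a threshold τ, chosen data-adaptively: among
candidate thresholds (the distinct max-posterior values), take the smallest
τ whose classified set has estimated misassignment proportion
`FAP(τ) = mean(1 - maxp)` at most α (default 5%) — i.e. classify as many
observations as possible subject to the constraint. The estimator is the
natural Bayesian-FDR analogue for clustering: `1 - maxp_i` is the posterior
probability that observation *i* is misassigned, so its mean over the
classified set estimates the misassigned fraction, and
`FAP × n_classified` the expected misassigned count. The comparison is
strict (`maxp > τ`). When no threshold satisfies the constraint nothing is
classified, with a warning.

This estimator is honest only insofar as the fitted posteriors are; the
validation suite therefore measures *true* misclassification on simulated
mixtures with known labels (three overlapping components, means about two
component standard deviations apart, distinct volumes, shared AR(1)-style
shape; n = 5000, 20 replicates — the `mixture_scenario("overlapping")`
conditions) and checks the 5% control within Monte-Carlo error.

`summarise_clusters()` reports per cluster and contrast the quartiles
(linear interpolation between order statistics — the common statistical
default; the choice only affects boxplot summaries), whiskers at
`Q1 - 1.5 (Q3 - Q1)` and `Q3 + 1.5 (Q3 - Q1)`, outliers outside them, and
the percentage of member genes DE per contrast. Clusters where no contrast
exceeds 50% DE membership are flagged uninterpretable and excluded from
biological reading.

## Positional cis-element (PLM) analysis

Promoters are the 1,000 bases upstream of the TSS, positions −1000…−1, with
−1 adjacent to the TSS. `scan_motif()` reports every exact IUPAC match
(Biostrings does the matching) anchored at the match base closest to the
TSS; by default both strands are scanned — probes sit on both strands and
catalogued motifs are often reported single-stranded — with
reverse-complement hits reported on the forward-strand window they occupy.
Overlapping matches are all reported; deduplication to gene level happens at
test time.

`detect_plm()` decides whether a motif is *preferentially located*: gene
occurrences are binned at 50 bp (20 bins), each bin's gene count is tested
against the uniform expectation by a one-sided binomial test with Bonferroni
correction over bins, and the functional window is the maximal run of
contiguous significant bins (ties broken by the smallest bin p-value). The
published PLM method's internals are not spelled out in the methods
literature this pipeline follows; this binned run detector is the package's
own operationalisation of "a functional window derived from the peak
boundaries of the over-represented region", chosen because its behaviour is
fully testable: planted windows are recovered, and uniform nulls are
declared at well below the nominal rate.

`test_cluster_enrichment()` then asks whether a cluster is enriched for
genes carrying the PLM inside its window: exact binomial upper tail with the
genome-wide windowed-hit proportion as `p0`, a gene counting at most once;
significance at p < 0.01.

## GO and kinetic-class enrichment

`hypergeom_enrichment()` is the classical one-sided hypergeometric
over-representation test, reported with the ratio of relative occurrences.
Matching the analysis convention this pipeline reproduces, the significance
flag uses the raw p < 0.05; a BH column is emitted alongside for users who
want FDR control. GO-slim mapping and graph propagation are out of scope —
the annotation table is taken as given.

`classify_kinetics()` assigns response-trajectory classes from linear-scale
fold changes at 1 h and 3 h. Induction means fold change ≥ 2 (the
discrimination rule's own granularity; configurable since the basal band is
not defined numerically in the source figure). Upregulated branch: F =
induced at 1 h only; G = induced at both, ≥ two-fold weaker at 3 h; H =
induced at both, within two-fold; I = induced at both, ≥ two-fold stronger
at 3 h; J = induced at 3 h only. A–E mirror F–J for repression on
reciprocal fold changes. Hence 10× then 15× is class H, and 10× then 50× is
class I. Genes induced at one time and repressed at the other are resolved
by branch precedence (induction first); genes never leaving the two-fold
band are unclassified. `class_enrichment()` reuses the hypergeometric
machinery with classes as terms.

## Interaction network and hubs

`build_network()` merges undirected PPI edges and directed TF→target edges
restricted to a gene universe (both endpoints must be in it), drops
self-loops and isolated nodes, and collapses duplicates — an a–b pair
present in both sources is one neighbour relation carrying both type tags.
Degree counts distinct neighbours regardless of type or direction, because
each edge represents one validated interaction; consistently, the hub rule
is strict: degree > 19 (20 interactions) makes a hub. Exports are SIF and
GraphML for external viewers.

## Pipeline, sizes and limitations

`run_pipeline()` chains the stages under a single validated configuration
(`pipeline_config()`) holding every threshold: DE α = 0.05, Bonferroni α =
0.05 for the clustering input, 1-log2 dependence rule, 5% assignment
control, PLM p < 0.01, GO p < 0.05, hub cutoff 19, 50% interpretability.
Outputs are TSV/JSON plus a manifest of all parameters, seeds and stage
counts; runs are byte-reproducible functions of the configuration (the
manifest deliberately contains no timestamps).

Simulation sizes used by the validation suite were chosen as the smallest
at which the asymptotic claims stabilise: n = 5000 observations and 20
replicates for the misclassification-control study, 10,000 genes for
variance-prior recovery, 2,000 promoters for PLM recovery, 50 replicates at
n = 1500 for the control-property sweep. The packaged demonstration
pipeline defaults to 2,000 genes.

Known limitations: the local-fdr estimator is a stand-in for kernel-based
optimised-FDR procedures and is the least-validated adjustment (hence BH as
default); the normal-null moderated test is anticonservative by
construction; the PLM detector's window resolution is its bin width; the
misclassification control is exact only in expectation under a
correctly-specified mixture; and none of the wet-lab-side analyses
(hormone quantification, bacterial growth, kinase assays) are in scope.
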