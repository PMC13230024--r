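---
title: "Methods: cross-cohort analysis of resistant-starch intervention microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort analysis of resistant-starch intervention microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Individual dietary-fiber intervention studies of the gut microbiome disagree
with each other: the same resistant-starch (RS) supplementation can appear to
raise, lower, or leave unchanged both diversity and the abundance of named
taxa, largely because cohorts differ in baseline composition, sequencing
region, depth, and design. **rsmeta** implements the analysis strategy that
addresses this: harmonize several paired (baseline/end-point) cohorts onto a
common feature space, remove subject-level baseline heterogeneity by working
strictly within individuals, and pool what remains across studies with
random-effects models that treat the study as the unit of heterogeneity.

The pipeline has six analysis stages over a shared data model (count tables,
sample metadata, a rooted feature phylogeny):

1. **Diversity meta-analysis** — per-study paired standardized mean
   differences of alpha diversity (Shannon, observed features, Faith's PD),
   pooled by REML random-effects meta-analysis.
2. **Distance-based testing** — repeated-measures PERMANOVA with
   permutations restricted to within-subject swaps, and unrestricted
   PERMANOVA for the variance explained by study.
3. **Paired differential abundance** — per-subject ΔCLR (end-point minus
   baseline centered log-ratio), per feature a study-random-intercept REML
   model, Benjamini–Hochberg control.
4. **Co-occurrence networks** — SparCC correlations per cohort and
   condition, permutation p-values, edge filtering, greedy modules, and a
   bounded node rewiring score combined across cohorts.
5. **Subject-aware classifier validation** — within-study CV, cross-study
   validation and leave-one-study-out (LOSO) random forests with
   subject-level fold integrity.
6. **Cross-disease validation** — a module abundance score (sum of relative
   abundances over the depleted feature set) compared across HC/CD/UC
   diagnoses with a study-random-effect mixed model, plus LOSO disease
   classifiers contrasting the full table with the module subset.

Every stage is exercised end to end by a synthetic multi-cohort generator
with known ground truth, so correctness claims are testable at desk scale.

## The synthetic data generator

`simulate_paired_cohorts()` draws, for subject $j$ of study $i$, feature
$k$, timepoint $t \in \{0, 1\}$, a latent log-weight

$$\eta_{ijkt} = \beta_k + u_{ik} + s_{ijk} + t\,\delta_k + \varepsilon_{ijkt},$$

with $\beta_k \sim N(0, \sigma_\beta^2)$ the community's rank-abundance
spread, $u_{ik} \sim N(0, \sigma_{study}^2)$ a study offset shared across
timepoints, $s_{ijk} \sim N(0, \sigma_{subject}^2)$ a subject offset shared
across the subject's two samples, and independent residual noise. Counts are
multinomial at a uniformly drawn sequencing depth, with proportions
$\mathrm{softmax}(\eta)$. This logistic-normal multinomial scheme is chosen
deliberately: the CLR of the latent weights is exactly the additive
structure the downstream random-intercept model assumes, so parameter
recovery is a meaningful check rather than a tautology. Because $u$ and $s$
are shared across a subject's two timepoints, strict pairing removes them —
the statistical motivation for analyzing within-individual change.

Defaults mirror the geometry of a seven-cohort RS meta-analysis: 7 studies
of 30 subjects, 200 features, a planted 22-feature module depleted by
$\delta = -0.8$ on the log scale, $\sigma_{study} = 0.5$,
$\sigma_{subject} = 1.0$, $\sigma_{noise} = 0.5$, depths 5,000–20,000.
$\sigma_\beta = 1.0$ is the package's choice where nothing is pinned: it
yields a realistic spread of common and rare features (per-feature counts
roughly 3–300 at these depths) without making module members so rare that
their counts are dominated by the pseudocount. The cross-sectional
generator plants diagnosis shifts CD $+1.0$ > UC $+0.4$ > HC $0$ on the
module, with study offsets shared across diagnosis groups.

What the generator does **not** emulate: 16S region-specific amplification
bias, taxonomy, chimeras, overdispersed (beyond logistic-normal) zero
inflation, and temporal drift within subjects. Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
model, not robustness to every artifact of real amplicon data.

### The compositional mirror effect

Depleting a module changes what the rest of the composition is measured
against. CLR values are log-abundances relative to the sample's geometric
mean; removing mass $\sum_k \delta_k$ from the module shifts the geometric
mean by $\sum_k \delta_k / p$, so every non-module feature acquires a small
*positive* ΔCLR mean ($+0.088$ at the defaults). With ~200 paired subjects
this diffuse mirror enrichment becomes statistically detectable: roughly
10–20 non-module features reach FDR < 0.05, all positive-signed. These are
real effects on the CLR scale, not errors — but they are not the planted
module. Consequently the package reports recovery of the **depleted
module** over the depletion-direction claim (significant *and* negative
pooled ΔCLR), for which sensitivity is 1.0 and the false-discovery
proportion 0 at the reference scenario, and reports the mirror-enriched
count alongside. This also explains, within the model, why a strictly
paired compositional analysis tends to surface a unidirectional depleted
set rather than matched enrichments.

## Statistical machinery and its approximations

**Paired effect size.** Hedges' g is the change-score standardized mean
difference: $d = \bar{\Delta} / s_\Delta$ with the $n-1$ denominator,
corrected by $J = 1 - 3/(4(n-1)-1)$, variance $1/n + g^2/2n$. Standardizing
by the SD of differences (rather than a pooled cross-sectional SD) matches
the within-individual framing; it makes g scale-free in the alpha metric,
so the log base of Shannon diversity (bits here) is immaterial.

**REML pooling.** `reml_pool()` maximizes the restricted likelihood of
$g_i \sim N(\mu, v_i + \tau^2)$ by bounded 1-D optimization with an
explicit check of the $\tau^2 = 0$ boundary; $\mu$ is the inverse-variance
weighted mean at $\hat\tau^2$, and inference is the normal (z)
approximation without a Knapp–Hartung small-$k$ adjustment. The z-interval
is advertised for mild-to-moderate heterogeneity: in simulations matched to
the design (7 studies, $v_i$ at the scale of 30-pair cohorts, between-study
SD ≈ 0.1, $I^2 \approx 0.2$) the 95% CI covers at ~94%; under strong
heterogeneity (between-study SD ≈ 0.2 at the same $v_i$) coverage drops to
~91%, the known cost of omitting the df correction.

**Random-intercept model.** `fit_random_intercept()` profiles the
restricted likelihood of $y_{ij} = \mu + b_i + e_{ij}$ over the variance
ratio $\lambda = \tau^2/\sigma^2$ on a log grid ($10^{-6}$–$10^4$, quarter-
decade steps) refined by bounded optimization to $10^{-10}$; $\mu$, both
variance components and the Wald z follow in closed form from per-study
sufficient statistics. Boundary fits ($\hat\tau^2 = 0$) are legitimate and
reported as such; with one study the model collapses to a one-sample z
test. The Wald-normal p-value is the main inferential approximation: at the
reference geometry (7 studies, 210 subjects) null p-values are uniform to
within KS distance ~0.06–0.08 and slightly conservative; at small $k$ and
$n$ the conservatism grows. `fit_diagnosis_lmm()` generalizes the same
engine to a fixed-effects design matrix (reference-coded diagnosis),
reporting marginal means at random effect 0 and BH-adjusted pairwise Wald
contrasts; module scores are analyzed on the raw proportion scale, matching
the percent reporting convention, with a logit transform available to users
who prefer it.

**Restricted permutations.** For paired designs the only permutations
preserving subject blocks of size two are within-subject label swaps —
equivalently sign flips of the paired structure. `rm_permanova()`
enumerates all $2^S$ flip patterns exactly when $2^S \le$ `n_perm`,
otherwise samples with $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$; the
add-one convention means p is never 0 and has resolution
$1/(n_{perm}+1)$. Its type-I error over 1,000 null replicates sits inside
[0.03, 0.07] at $\alpha = 0.05$.

**SparCC.** Per Dirichlet resample (parameters counts + 1), log-ratio
variances $t_{ab}$ are formed from the covariance of log-fractions; basis
variances solve the sparsity-assumption linear system (diagonal = included
degree, off-diagonal 1 for included pairs); the most strongly correlated
pair is excluded and the system re-solved, up to 10 iterations or until the
strongest candidate falls below 0.1 — the original algorithm's conventions,
since nothing else is printed. The final matrix is the elementwise median
of 20 resamples clipped to $[-1, 1]$. Permutation p-values shuffle each
feature's counts independently and recompute a single-resample point
estimate, trading inner resampling for permutation count. Features below
10% prevalence are excluded before estimation. Non-positive basis
variances (possible under aggressive exclusion) yield NA correlations with
a warning rather than fabricated values.

**Rewiring score.** The upstream tool's score is not published as a
formula, so the package defines a bounded, testable one: with
within-module absolute strength $s_A(i)$ (sum of $|r|$ over retained edges
to same-module partners) in condition A and $s_B(i)$ in B,
$\mathrm{score}_i = |s_B - s_A| / (s_A + s_B + 10^{-9}) \in [0, 1)$. Scores
are combined across cohorts as a sample-size-weighted mean (a convex
combination), and the strong-rewiring flag uses the 0.12 threshold. Module
partitions come from greedy modularity maximization on absolute weights of
the union graph, so baseline and end-point are compared on one node
universe.

**Classifier validation.** Random forests use 500 trees and library
defaults, with class-probability scores feeding a midrank Mann–Whitney
AUC. Folds are dealt at the subject level (seeded shuffle, round-robin, ±1
subject imbalance tolerated), and a structural assertion verifies no
subject ever spans train and test. CV pools held-out scores into a single
per-study ROC; cross-study models are fit once on the whole training study
rather than refit per fold; LOSO pools all other studies. Taxonomic
features enter as per-cohort CLR values on the shared feature set
(consistent with the differential abundance stage); relative abundances
are available behind a flag and are used for the cross-sectional disease
classifiers, where the module score itself lives on the proportion scale.

## Numerical and design choices

- **Thresholds** all default to the analysis constants: depth floor 1,000
  reads; rarefaction depth 1,000 (single seeded draw, without replacement —
  multiple rarefaction is out of scope); prevalence 10% with
  $\lceil f \cdot n \rceil$ rounding and detection = count > 0; CLR
  pseudocount 1; FDR 0.05; edge thresholds $|r| \ge 0.1$ (inclusive) and
  $p < 0.05$ (strict); rewiring flag 0.12; 999 permutations; 5 folds; 500
  trees.
- **Rarefaction order**: samples are depth-filtered first, and rarefied
  tables feed *only* the diversity stages; differential abundance uses raw
  counts through the CLR.
- **Feature universe for cross-cohort testing**: the pooled 10% prevalence
  rule defines the tested set in `run_pipeline()`; each cohort is
  CLR-transformed on its own surviving features and pairs are differenced
  on the shared set. Predicted-function tables (KO, CAZyme) pass through
  the identical machinery and the identical prevalence rule.
- **Ties and sorting**: differential abundance results order by
  $(q, -|\hat\mu|, \text{feature})$; core-subnetwork driver selection
  breaks score ties by abundance, then feature id — all output files are
  byte-reproducible under a fixed seed.
- **Degenerate inputs**: zero-variance paired differences and all-equal
  responses are errors or flagged degenerate fits (μ reported, p = NaN),
  never silent zeros; zero-sum samples are errors in
  `relative_abundance()`; empty filter results warn.
- **Exact-vs-approximate switchovers** for the rank tests follow the
  standard implementation (exact for small untied samples, midrank normal
  approximation with continuity and tie corrections otherwise); both
  branches are verified against exhaustive enumeration oracles in the test
  suite.
- **Seeds**: every stochastic step takes an explicit seed;
  `run_pipeline()` expands one global seed into per-stage seeds via
  `seed * 131 + stage` so stages can be re-run in isolation.

## Problem sizes used by the tests

The reference recovery scenario (7 × 30 subjects, 200 features, 22-feature
module) runs in seconds and is used directly in the acceptance checks; the
stochastic calibrations use 1,000 null PERMANOVA replicates at 10 subjects,
20 classifier seeds at 3 × 14 subjects with 120-tree forests, 500 simulated
meta-analyses, and 200 mixed-model coverage fits at 5 × 40 samples. These
sizes are the package's calibration choices: large enough that binomial
noise on a rate sits well inside the asserted bands, small enough to keep
the suite interactive.

## Known limitations

- Wald-z inference (no Satterthwaite/Kenward–Roger df, no Knapp–Hartung)
  undercovers under strong between-study heterogeneity with few studies.
- The combined repeated-measures PERMANOVA blocks by subject but does not
  additionally model study as a fixed term; study structure is reported
  separately via the unrestricted study-variance test.
- CLR-scale inference inherits the compositional mirror effect described
  above; module recovery statements are direction-aware.
- SparCC permutation p-values use a single inner resample per permutation;
  raise `n_resamples` and `n_perm` for publication-grade networks.
- The generator's multinomial noise underestimates the overdispersion of
  real amplicon counts; absolute false-positive rates on real data may
  differ from the calibrated values reported here.
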