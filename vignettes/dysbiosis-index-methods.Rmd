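---
title: "Scoring gut dysbiosis against a normobiotic PCA reference model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gut dysbiosis against a normobiotic PCA reference model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiosr)
```

## The problem

Chronic liver disease — and cirrhosis in particular — is accompanied by a
characteristic distortion of the gut microbiome: opportunistic taxa expand
while short-chain-fatty-acid producers such as *Bifidobacteria* recede.
Interventions that target the microbiome (probiotics, prebiotics,
synbiotics) need a scalar readout of how far a patient's microbial
composition deviates from health, both to quantify baseline dysbiosis and to
track whether treatment moves patients back toward the healthy state.

dysbiosr implements such a readout, the **Dysbiosis Index (DI)**, using the
machinery of PCA-based multivariate statistical process control (MSPC): a
"normobiotic" reference model is fitted to healthy-control profiles, and any
sample is then scored by how far it sits outside that model's confidence
region.

## The reference model and its statistics

Let $X$ be the $n \times d$ matrix of transformed abundances of $n$ healthy
reference samples over $d$ features. The model stores the reference mean
$\bar{x}$ (and optionally per-feature standard deviations for autoscaling),
and the PCA of the centred matrix via SVD: loadings $P \in \mathbb{R}^{d
\times k}$ and eigenvalues $\lambda_1 \ge \dots \ge \lambda_d$ with
$\lambda_i = s_i^2/(n-1)$. The retained dimension $k$ is the smallest count
whose cumulative variance reaches `variance_target` (default 0.90), capped
at $\min(n-2,\, d-1)$; ties at the target resolve to the smallest $k$, and
the sign of each loading column is fixed by making its largest-magnitude
entry positive, so fits are deterministic.

A sample $x$ is centred to $\tilde{x}$, projected to scores $t = P^\top
\tilde{x}$, and summarised by two complementary statistics:

* **Hotelling's $T^2$** $= \sum_{i \le k} t_i^2 / \lambda_i$ — Mahalanobis
  distance *inside* the model plane: how unusual the sample is along the
  directions of normal healthy variation.
* **$Q$ (squared prediction error)** $= \lVert \tilde{x} - P t \rVert^2$ —
  distance *off* the model plane: variation in directions healthy samples do
  not use.

Their $(1-\alpha)$ confidence limits under the reference distribution are
the classical MSPC forms: the new-observation $F$ limit

$$T^2_{\lim} = \frac{k\,(n-1)(n+1)}{n\,(n-k)} \, F_{1-\alpha}(k,\; n-k),$$

and the Jackson–Mudholkar approximation for $Q$ from the residual
eigenvalue moments $\theta_i = \sum_{j>k} \lambda_j^i$,
$h_0 = 1 - 2\theta_1\theta_3/(3\theta_2^2)$:

$$Q_{\lim} = \theta_1 \left[ \frac{z_{1-\alpha}\sqrt{2\theta_2 h_0^2}}{\theta_1}
 + 1 + \frac{\theta_2 h_0 (h_0 - 1)}{\theta_1^2} \right]^{1/h_0}.$$

If the retained components absorb all variance ($\theta_1 = 0$), $Q$ carries
no information; the limit is set to 0 and $Q$ scoring is disabled with a
warning.

### The DI combination rule

The two statistics answer different questions, so the index must combine
them. The default is the normalised symmetric mean

$$\mathrm{DI} = \frac{1}{2}\left( \frac{T^2}{T^2_{\lim}} +
\frac{Q}{Q_{\lim}} \right),$$

so that DI $> 1$ means the sample exceeds the normobiotic confidence range
on average across the two charts. This was a genuinely open design choice:
any monotone combination of the two normalised statistics is defensible, and
which one a given study used is rarely recoverable from its figures. We
therefore report $T^2$, $Q$ and both limits alongside DI, and
`score_samples(..., combine =)` selects `"max"`, `"t2"` or `"q"` instead;
nothing downstream depends on the choice beyond the DI column itself.

### Input space

PCA with elliptical confidence regions presumes approximately Euclidean
geometry, which raw relative abundances (points on a simplex) do not have.
The default pipeline therefore closes each sample to relative abundances and
applies the centred log-ratio (CLR) transform with a pseudocount of half the
smallest nonzero relative abundance — the standard multiplicative-replacement
heuristic. A plain `log`-relative transform is available via
`transform_abundance(method = "log-relative")` for users who want abundance
changes, not ratio changes, to drive the index. The pseudocount and
transform are locked into the fitted model so held-out samples are always
transformed identically. Features observed in fewer than 10% of reference
samples are dropped before fitting (`min_prevalence = 0.1`); near-absent
features contribute almost pure sampling noise to the residual space and
inflate $Q$ for everyone.

### Calibration in practice

The $F$ and Jackson–Mudholkar limits are *training-data* forms: they are
exact for multivariate-normal data with the model's true subspace, and
approximate once $k$ and the eigenvalues are themselves estimates. Two
consequences matter for interpretation:

* On data that genuinely follow the reference distribution, held-out
  exceedance rates converge to $\alpha$; with moderate reference sizes the
  top eigenvalues are slightly over-estimated, which biases the $T^2$ rate a
  few tenths of a percent below nominal. The test suite measures both rates
  on 200-sample references from a known 20-feature normal (retention forced
  to $k = 5$, 10,000 held-out scores) and requires $\alpha \pm 0.01$ for
  $T^2$ and $\alpha \pm 0.015$ for $Q$.
* On real CLR microbiome profiles — which are not multivariate normal, and
  where $d$ may exceed $n$ — held-out healthy samples typically score above
  the training-based limits (median DI around 2 in our synthetic cohorts).
  DI is therefore best read *comparatively* (patients versus healthy
  controls scored with the same model), which is how the group-comparison
  stage uses it.

## The surrounding stages

**Group comparison.** DI distributions are compared with the Kruskal–Wallis
test (mid-ranks, tie correction, $\chi^2$ approximation — group sizes in the
intended uses exceed 20) and Dunn's post-hoc pairwise $z$ tests on the
pooled ranks, with Bonferroni (default) or Benjamini–Hochberg adjustment.
These wrap or follow the standard formulas exactly; the suite checks them
against independent rank-formula computations.

**Discriminatory taxa.** `lda_effect_size()` follows the LEfSe recipe:
a per-feature Kruskal–Wallis gate at `kw_alpha` (default 0.05), then for
surviving features a one-against-all linear discriminant on bootstrap
subsamples (30 rounds, two-thirds of each class per round), computed on
abundances rescaled monotonically onto $[1, 10^6]$ so the conventional
"LDA score (log10) > 2" threshold keeps its usual meaning. The within-class
covariance is ridge-regularised by $10^{-6}$ of its trace, which keeps the
discriminant well-posed at bootstrap class sizes of a handful of samples. No
subclass (within-class) stage is implemented: the four-arm design this
package targets has flat groups. One caveat the simulations make visible:
after compositional closure, a large abundance shift in one taxon perturbs
*every* relative abundance, so "null" features are not exactly null and the
gate can run slightly above its nominal level when the shifted taxon is
abundant.

**Correlations.** `spearman_matrix()` computes Spearman's $\rho$ on
mid-ranks for all cross-set feature pairs with the $t$-approximation
p-value, BH adjustment across the whole family, and a `kept` flag at the
chosen threshold. Both filtering conventions found in practice — BH-adjusted
and raw $p < 0.05$ — are supported (`adjust =`), defaulting to BH. The
$t$ approximation is accurate for the cohort sizes intended ($n \ge 10$);
constant features are reported as missing rather than silently dropped.

## The synthetic trial generator

`generate_trial()` exists so every stage can be exercised end-to-end with no
sequencing data. It emulates the structure of a four-arm synbiotic trial in
cirrhosis: a healthy reference cohort (n = 50) for fitting, a held-out
healthy test cohort (n = 30), a baseline patient arm (NIP, n = 57), and
Placebo (n = 21) / Synbiotic (n = 29) arms.

The model is log-normal-latent + multinomial: taxon $j$ has a baseline
log-mean $\mu_j \sim \mathcal{N}(0, 1.5^2)$ (a long-tailed rank-abundance
curve after exponentiation); each sample draws latent values
$z_j \sim \mathcal{N}(\mu_j + \delta_j^{(\mathrm{arm})},\, 0.5^2)$ and counts
from a multinomial over $\mathrm{softmax}(z)$ with total
$\sim \mathrm{Poisson}(50{,}000)$. Dysbiosis adds $\pm\delta$ (default
$\delta = 1.0$, i.e. two latent standard deviations) to a random 20% of
taxa — half up, "opportunist-like"; half down, "beneficial-like" — in the NIP
and Placebo arms; the Synbiotic arm receives $(1-\rho)\delta$ with reversion
$\rho = 0.7$ by default, i.e. a substantial but incomplete return toward the
healthy configuration. This latent-layer construction was chosen over a
Dirichlet-multinomial because it gives direct, signed control of per-taxon
effects (the ground truth is returned alongside the tables) while still
producing overdispersed counts.

What the generator does *not* emulate: phylogenetic correlation between
taxa, sparsity patterns of real shotgun profiles beyond what the long tail
induces, per-sample depth artefacts, or subject-level longitudinal pairing.
Passing tests on this generator show the statistical machinery is correct
and well-calibrated under its stated assumptions — not that any particular
clinical dataset will separate as cleanly.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale problem sizes chosen
to make Monte-Carlo error small relative to the tolerances: calibration on
10 independent 200-sample references with 10,000 held-out scores in total;
100 replicate trials for the DI separation pattern; 50 replicates per
reversion level; 10,000 null simulations for the Kruskal–Wallis rejection
rate; 50 replicate two-group tables of 200 features for effect-size
detection; 50 replicate cohorts of 100 samples for correlation recovery.

Other conventions, fixed once: sample (n−1) standard deviations everywhere;
smallest-$k$ tie-break for the variance target; deterministic loading signs;
group labels sorted before seeded subsampling so effect-size results are
invariant to sample order; the DI of the exact reference centroid is 0 by
construction.

## Known limitations

* The training-data limits make absolute DI values conservative for
  held-out real-world samples (see *Calibration in practice*); comparisons
  between groups scored under one model are unaffected.
* Rarefaction is deliberately not implemented; closure to relative
  abundance replaces it, which is sufficient for every downstream statistic
  in this package but means depth-dependent detection artefacts are not
  modelled.
* The LDA effect size is reported per feature without taxonomic-hierarchy
  propagation or cladogram output.
* `spearman_matrix()` computes plain (not partial) Spearman correlations.
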