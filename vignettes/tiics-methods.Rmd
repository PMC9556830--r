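---
title: "Composite immune infiltration scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite immune infiltration scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiicscore)
```

## The model

`tiicscore` scores the prognostic content of the tumor immune
microenvironment from bulk expression in four steps.

**Per-sample enrichment.** For each sample, genes are ranked by expression
(ascending; tied values receive average ranks) and walked in order of
decreasing rank. The enrichment score of a signature $S$ is

$$ES(S) = \sum_{i=1}^{N}\left[P_{in}(i) - P_{out}(i)\right],\qquad
P_{in}(i) = \frac{\sum_{g \in S,\,pos(g)\le i} r_g^{\alpha}}
                 {\sum_{g \in S} r_g^{\alpha}},\qquad
P_{out}(i) = \frac{|\{g \notin S,\,pos(g)\le i\}|}{N - |S|},$$

with $r_g$ the absolute rank (1..N) and $\alpha = 0.25$, the conventional
single-sample GSEA weighting. Because each gene contributes to the running
sums at every position at or after its own, the double sum collapses to a
per-gene form ($\sum_i P_{in}(i) = \sum_{g\in S} r_g^\alpha (N - pos_g + 1)
/ W$), which the implementation evaluates as three matrix products; the
test suite checks it against a literal double-loop reference to $10^{-9}$.

**Screening.** One univariate Cox proportional-hazards fit per cell type
(Efron tie handling) on the cell's enrichment row; cell types with Wald
$P < 0.05$ are retained.

**The composite score.** Each retained cell type contributes its
enrichment weighted by effect size over estimation precision:

$$\mathrm{TIICs}_j = \sum_i \frac{1 - HR_i}{SE(HR_i)}\, ES_{ij}.$$

Protective cell types ($HR<1$) get positive weights, harmful ones
negative, so a high composite score always means a favorable expected
outcome. The cohort is split at the median score; samples tied with the
median go to the low group (deterministic, and "high" then means strictly
above the cutoff; the opposite convention is available via `ties =
"high"`).

**Evaluation.** Kaplan–Meier curves and the log-rank test compare the
groups; cumulative/dynamic time-dependent AUC with inverse-probability-of-
censoring weights measures discrimination of "event by $t$" versus
"survivor past $t$"; a multivariate Cox fit with a Breslow baseline yields
survival predictions at the 6/8/10-year horizons (72/96/120 months — all
times in this package are months).

## Key parameters

| parameter | default | rationale |
|---|---|---|
| `alpha` (ssGSEA exponent) | 0.25 | single-sample GSEA convention; 0 gives an unweighted CDF difference |
| `normalize` | TRUE | global (max−min) normalization of the score matrix, the "ssgsea.norm" convention; normalized scores feed the Cox screen and the composite (raw scores available) |
| screening `p_threshold` | 0.05 | conventional univariate screen level |
| correlation `p_threshold` | 1e-4 | retention level for the cell–cell network edges |
| `k_clusters` | 4 | cell types fall into a small number of co-infiltration groups |
| `min_set_size` | 5 | enrichment of tiny sets is rank-noise dominated |
| DEG thresholds | \|logFC\| > 0.5, raw $P$ < 0.05 | the declared significance rule; BH-adjusted p-values are reported alongside but never filter |
| AUC horizons | 72, 96, 120 months | 6/8/10-year survival read-outs |

Two genuinely open choices are exposed rather than hidden. First, the
$SE(HR)$ in the weight denominator is interpreted by the delta method
($HR \cdot se_\beta$); the log-scale $se_\beta$ alternative is available
via `compute_weights(se = "beta")` — it rescales weights but never changes
their sign, so stratification direction is unaffected. Second, external
validation defaults to *refit* mode (weights re-estimated on the
validation cohort, i.e. the score is calculated the same way), with
*transfer* mode (training weights reused) available; both are supported
because either reading of "validated in the same way" is defensible.

## The synthetic cohort generator

`generate_cohort()` draws, per cell type $k$ and sample $j$, a latent
infiltration level $a_{kj} \sim N(0,1)$. Genes in cell $k$'s signature
follow $x_{gj} = \mu_g + \lambda a_{kj} + \varepsilon$; background genes
are $\mu_g + \varepsilon$, with $\mu_g \sim N(6,1)$ (a log2-microarray-like
scale) and $\varepsilon \sim N(0, \sigma^2)$. A second pseudo-cohort batch
can add a location shift and a noise-scale factor. Event times are
exponential with rate $h_0 \exp(\sum_k \beta_k a_{kj})$ — the simplest
distribution consistent with proportional hazards — and censoring times
are exponential with their rate calibrated by root-finding so the expected
censored fraction matches `censor_rate`. Defaults: 28 cell types of 20
genes in a 1000-gene universe, $\lambda = 1$, $\sigma = 1$, $h_0 = 0.01$
events/month (median survival near six years on the null), 30% censoring.
Signature sets are disjoint by default; `overlap_frac` plants shared genes
between neighboring sets, since real signatures overlap.

What the generator does *not* emulate: heavy-tailed or platform-specific
intensity distributions, correlated background genes, non-proportional
hazards, informative censoring, and real signature overlap structure.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not robustness to everything
real cohorts do.

## Numerical choices

- **Rank ties** get average ranks for the weights, but positions along the
  walk are resolved by lexicographic gene id — scores on discrete
  (rounded) data are exactly reproducible.
- **Cox fits** use Efron's tie correction, convergence tolerance $10^{-9}$,
  at most 50 iterations; monotone-likelihood (perfect separation) fits are
  returned but flagged `converged = FALSE`.
- **Time-dependent AUC** is the cumulative/dynamic IPCW estimator: case
  weights $1/\hat G(T_i^-)$, control weights $1/\hat G(t)$, where
  $\hat G$ is the Kaplan–Meier estimate of the censoring distribution;
  tied marker values count one half. Without censoring it reduces exactly
  to the binary ROC AUC, which the tests exploit as an oracle. In
  `compare_auc()` every marker is first oriented to its risk direction
  (the composite is negated; protective cells' rows are negated), so AUCs
  are comparable across markers.
- **Median split** on an even cohort uses the mean of the two central
  order statistics, as does probe collapsing for even probe counts.
- **Preranked enrichment** breaks statistic ties by gene id, uses
  $|stat|$ weights, a gene-label permutation null, signed-mean NES, and a
  two-sided permutation p-value with a +1 pseudo-count.
- **Batch adjustment** is parametric empirical-Bayes location/scale
  adjustment (ComBat) without covariates. Note that shrinkage leaves
  per-gene sampling noise in place: after removing a pure batch shift the
  *systematic* (across-gene) batch gap vanishes, but individual genes
  retain gaps of order $\sqrt{2/n}$ — as they would even if the true shift
  were subtracted exactly. Tests assert the systematic gap and compare the
  per-gene residual against that oracle bound.

## Known limitations

**Compositional coupling of single-sample scores.** ssGSEA scores of
different signatures within a sample are not independent: if one
signature's genes move up the ranking, every other signature's genes
necessarily move down. With a strongly prognostic planted cell, the other
27 "null" cells acquire a small real association with survival (enrichment
correlations near −0.03, hazard ratios slightly above 1), and marginal
univariate screening selects them somewhat above the nominal 5% rate.
This is a property of the scoring method, not of the screen; on fully
null cohorts the screen holds its size. Co-selected cells enter the
composite with small weights and dilute it only mildly.

**Moderated-t limiting behavior.** The moderated t converges to the
per-gene pooled t as the residual degrees of freedom grow *when the true
gene variances are heterogeneous* (finite shrinkage prior). When variances
are exactly exchangeable the empirical-Bayes machinery correctly estimates
an infinite prior and fully squeezes toward the common variance — the
right behavior, but not per-gene convergence. The convergence test uses
inverse-chi-square distributed true variances, the shrinkage model's own
prior.

**Purity transform scale.** The ESTIMATE purity transform
$\cos(0.6049872018 + 0.0001467884\,\times\,\text{estimate score})$ was
calibrated on Affymetrix-scale scores; on other scales the package warns
and clips the reported purity to $[0,1]$, keeping the raw cosine in
`purity_raw`.

## Problem sizes in the test suite

The statistical acceptance checks run at the scale the properties are
stated for: Cox recovery at $n = 1000$ with 100 replicates per
coefficient; log-rank null uniformity over 1000 replicates of $n = 100$;
composite-score sign recovery and screening power over 100 replicates of
$n = 800$ cohorts (28 signatures, 600 genes); screening size over 60 null
cohorts; differential-expression calibration on 2000 genes at $n = 50$ per
group. The full suite completes in a few minutes on a single core.
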