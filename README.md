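# tiicscore

Composite tumor immune cell infiltration scoring (TIICs) for prognostic
stratification of bulk expression cohorts.

## The problem

The composition of the tumor immune microenvironment carries prognostic
information: in plasma-cell malignancies and many solid tumors, the degree
to which particular immune cell types infiltrate the tumor associates with
overall survival. Given only bulk gene expression and follow-up data, one
can estimate per-sample infiltration of each immune cell type from its gene
signature, ask which cell types are prognostic, and combine them into a
single per-patient score.

`tiicscore` implements that workflow end to end:

1. **ssGSEA** — per-sample enrichment of each immune cell signature: genes
   are ranked within the sample and the score of set *S* is
   ES(S) = Σᵢ [P<sub>in</sub>(i) − P<sub>out</sub>(i)], where
   P<sub>in</sub> weights in-set genes by rank<sup>α</sup> (α = 0.25) and
   P<sub>out</sub> is the out-of-set empirical CDF.
2. **Cox screening** — one univariate proportional-hazards fit per cell
   type; cell types with Wald *P* < 0.05 are retained.
3. **The composite score** — for each sample *j*,

   TIICs(j) = Σᵢ (1 − HRᵢ) / SE(HRᵢ) × ESᵢⱼ

   over the retained cell types: protective cells (HR < 1) enter with
   positive weight, harmful ones negative, each scaled by its estimation
   precision.
4. **Stratification and evaluation** — median split into high/low groups;
   Kaplan–Meier curves, log-rank test, IPCW time-dependent AUC of the
   composite versus each single cell type, multivariate Cox with
   6/8/10-year survival prediction.
5. **Group characterization** — ESTIMATE-style stromal/immune/purity
   scores, limma moderated-t differential expression
   (|logFC| > 0.5, *P* < 0.05), preranked permutation set enrichment and
   Wilcoxon feature comparisons between the score groups.

A synthetic-cohort generator (`sim_config()` / `generate_cohort()`) with
planted signature sets, latent infiltration levels, batch effects, and
proportional-hazards survival provides ground truth for every stage, so the
whole pipeline is testable without any external download. Probe-to-gene
median collapsing (`collapse_probes()`) and empirical-Bayes batch
adjustment (`batch_adjust()`, ComBat) cover preprocessing of
multi-cohort array data.

## Worked example

```r
library(tiicscore)

cfg <- sim_config(n_samples = 400, signal_strength = 2,
                  prognostic_cells = c(cell_05 = -0.7, cell_12 = -0.5),
                  seed = 42)
cohort <- generate_cohort(cfg)

es  <- ssgsea_score(cohort$expression, cohort$signatures)
fit <- build_tiics(es, cohort$survival)
fit$weights
#>   cell_type        HR      se_HR      p_value    weight
#> 1   cell_05 0.1019498 0.02539858 4.952128e-20 35.358278
#> 2   cell_12 0.3571131 0.08634837 2.057413e-05  7.445269
#> 3   cell_22 0.5864299 0.13561706 2.100950e-02  3.049544
#> 4   cell_27 0.6196396 0.14870329 4.611103e-02  2.557848

lr <- logrank_test(cohort$survival, fit$scores$group)
sprintf("log-rank chi-square = %.1f, p = %.3g", lr$chi_square, lr$p_value)
#> "log-rank chi-square = 74.4, p = 6.28e-18"

compare_auc(fit$scores$score, es, fit$weights, cohort$survival,
            horizons = c(24, 48))
#>           t24   t48
#> TIICs   0.727 0.728
#> cell_05 0.698 0.698
#> cell_12 0.613 0.624
#> cell_22 0.572 0.563
#> cell_27 0.531 0.557
```

Both planted protective cells are recovered with HR < 1 and positive
weights (two weakly co-selected cells ride along — see the vignette on
compositional coupling of single-sample scores). The high-TIICs group has
markedly better survival, and the composite score discriminates 24- and
48-month outcomes better than any single cell type.

`run_pipeline()` chains every stage on one cohort (including the
microenvironment scoring and differential expression) and can write all
stage tables plus an md5 manifest; `validate_external()` applies a trained
score to an independent cohort in refit or transfer mode.

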