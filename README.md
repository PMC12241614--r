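# netage

Individual-specific gene regulatory networks and aging signatures in R.

## The problem

Bulk-tissue cohorts show that the way transcription factors (TFs) target
genes shifts with age — some genes become more heavily regulated, others
less — and that this drift accelerates with smoking history, resembles the
regulatory shifts seen in lung tumors, and carries prognostic information
that chronological age does not. Detecting these shifts requires a
regulatory network *per individual*, not one network per cohort. `netage`
implements that full analysis chain for computational biologists who want to
run or stress-test it end to end:

1. **Priors** — a binary TF×gene motif prior from motif-hit intervals
   falling in promoter windows `[TSS − 750, TSS + 250]` (strand-mirrored),
   made sex-specific by zeroing chrY edges; a symmetric TF×TF interaction
   prior on [0, 1] with unit diagonal; TPM-style expression filtering.
2. **Network inference** — PANDA-style message passing: the motif prior is
   iteratively reconciled with TF–TF cooperativity and gene coexpression
   through a continuous Tanimoto kernel,
   `W ← (1−α)W + α(R + A)/2`, until the mean absolute edge change drops
   below tolerance. LIONESS-style single-sample networks follow by linear
   interpolation: `e(q) = N(e_all − e_−q) + e_−q`.
3. **Differential targeting** — per-gene covariate-adjusted linear models of
   the targeting score (indegree, the sum of incoming edge weights) on age,
   disease status, or an age×smoking interaction, with empirical-Bayes
   moderated t-statistics; smoking-stratified aging trajectories over 20
   age-quantile bins.
4. **Enrichment** — pre-ranked GSEA on the age t-statistics with a
   random-gene-set null (exact enumeration when feasible) and
   Benjamini–Hochberg correction.
5. **Aging signature** — pathway targeting scores (first principal component
   of each pathway's indegree block), a LASSO-penalized Cox model over those
   scores with 10-fold cross-validation and the lambda-1SE rule, and
   evaluation by median-split Kaplan–Meier / log-rank and adjusted Cox fits.
6. **Drug matching** — reversal scoring of up/down differential-targeting
   gene lists against a drug regulatory-signature library, with an empirical
   p-value from 10,000 size-matched resampled inputs.

A synthetic-cohort generator (`cohort_spec()`, `generate_cohort()`,
`generate_survival_cohort()`, `generate_drug_library()`) plants known
age-coupled co-regulation, pathway-driven hazards and reversal drugs, and
records the ground truth, so every stage is testable offline.

## A worked example

```r
library(netage)

spec   <- plant_genes(cohort_spec(seed = 7), n_up = 15, n_down = 10)
cohort <- generate_cohort(spec)
cohort
#> synthetic cohort: 20 TFs, 200 genes, 120 samples
#>   planted: 15 up / 10 down genes; age slope 0.02; 12 pathways

net <- infer_sample_networks(cohort$expression, cohort$motif_prior,
                             cohort$ppi_prior, cohort$covariates,
                             cohort$annotations)
dt <- diff_targeting(net$indegree, cohort$covariates, model = "age")
print(dt, n = 3)
#> differential targeting (age coefficient): 200 genes, 120 samples
#>      gene       slope t_ordinary p_ordinary t_moderated p_moderated ...
#> 140 g0140  0.11292410   2.159600 0.03295547    2.289583  0.02321214
#> 45  g0045  0.09800281   2.117679 0.03643458    2.156486  0.03237931
#> 94  g0094 -0.09574177  -2.113409 0.03680615   -2.135582  0.03407231
```

`net$indegree` is the gene × sample targeting-score matrix; `dt` holds each
gene's age slope (the change in indegree per year of age — here ~0.1
indegree units/year for the top genes), ordinary and moderated t, p and
FDR. Genes planted to gain TF targeting with age surface with positive
slopes, planted losers with negative ones. Downstream:

```r
sel <- select_age_genes(dt, p_threshold = 0.05)     # up / down gene lists
gsea_preranked(setNames(dt$t, dt$gene), cohort$gene_sets, min_size = 5)
tr  <- aging_trajectory(net$indegree, cohort$truth$planted_up,
                        cohort$covariates)          # ever vs never slopes
md  <- match_drugs(sel$up, sel$down, cohort$drug_library,
                   universe = rownames(net$indegree))
```

For the survival arm, `generate_survival_cohort()` produces pathway
targeting scores with four hazard-active pathways among 28;
`aging_signature_fit()` selects pathways by lambda-1SE penalized Cox, and
`predict()` returns each sample's aging signature:

```r
sc  <- generate_survival_cohort(n_samples = 400, seed = 1)
fit <- aging_signature_fit(sc$scores, sc$time, sc$event, n_folds = 10, seed = 1)
fit
#> aging signature: 4 of 28 candidate pathways selected (lambda 1se = 0.1541)
#>    pw01    pw02    pw03    pw04
#>  0.1651  0.2566 -0.2809 -0.2553
km_logrank(sc$time, sc$event, predict(fit, sc$scores))
#> log-rank test: chi-square = 149.880 (1 df), p = 1.842e-34
```

The four selected pathways are exactly the planted hazard-active ones, the
coefficient signs match the planted hazard directions, and samples above
the median fitted signature die markedly faster than those below it.

The whole chain also runs file-based from one configuration via
`run_pipeline()`, which writes every intermediate artifact plus a JSON
manifest with seeds, parameters and checksums.

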