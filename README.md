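# proxiscore

Does one cell type preferentially sit next to a particular subtype of
another in tissue? `proxiscore` answers that question for single-cell
resolved spatial transcriptomics data, in the setting where an annotated
single-cell reference exists but the spatial cells still need labels. It was
built around a concrete use case from ischemic muscle disease — asking
whether tissue-resident `LYVE1`hi MHCIIlow macrophages crowd around specific
endothelial-cell (EC) subtypes in peripheral artery disease — but every step
is generic.

## What it computes

1. **kNN label transfer** (`transfer_labels()`): each spatial cell receives
   the most frequent cluster label among its k = 10 nearest reference cells,
   by Euclidean distance in a shared 2-D embedding (e.g. a joint t-SNE after
   integration). Ties are broken deterministically (closer class, then
   lexicographic).
2. **Proximity score** (`nearest_target()`, `expected_proportions()`,
   `proximity_scores()`): within each sample, every query cell is mapped to
   its nearest target cell in tissue coordinates. For target subtype *s*
   with observed count *O_s* among *n* query cells, the score is

       score_s = O_s / (n * p0_s),   p0_s = (# target cells of subtype s) / (# target cells)

   so `p0_s` is subtype *s*'s share of all target cells in the sample — the
   chance expectation for uniformly placed query cells. A score above 1
   means the query cells are closer to subtype *s* than expected by chance.
   Significance is an exact one-tailed binomial test,
   `P(X >= O_s), X ~ Binomial(n, p0_s)`, pooling counts across each
   condition's samples (count-weighted pooled `p0`); per-sample scores are
   summarised as mean ± s.e.m. across samples.
3. **Cluster composition** (`composition()`): per-sample cluster proportions
   with condition mean ± s.e.m., or condition-pooled proportions.
4. **Gene-set change fraction** (`change_fraction()`): the percentage of a
   curated gene set (e.g. the core matrisome) intersecting a changed-gene
   list, rounded half-away-from-zero to one decimal.

A synthetic-data generator (`synth_config()`, `generate_cohort()`) produces
matched reference/spatial cohorts with known ground truth — Gaussian cluster
clouds in the embedding, uniform cell placement in a square tissue domain,
and a tunable planted attraction of the query cell type toward one target EC
subtype — so the whole pipeline is testable without any downloads.

## Worked example

The default configuration emulates a two-condition study (three patients per
condition, 2000 reference and 2000 spatial cells each) in which macrophages
are attracted to the `ATF3/ATF4+ venous EC` subtype only in the `PAD`
condition:

```r
library(proxiscore)
cfg <- default_pipeline_config(seed = 1, outdir = "proxiscore_out")
res <- run_pipeline(cfg)
subset(as.data.frame(res$proximity$per_condition),
       target_subtype == "ATF3/ATF4+ venous EC",
       c(condition, pooled_observed, pooled_n, pooled_p0, pooled_score, p_value))
```

```
     condition pooled_observed pooled_n pooled_p0 pooled_score   p_value
1          PAD             360      919 0.1188766    3.2948820 1.180e-98
7 non-ischemic             100      894 0.1135251    0.9854292 5.775e-01
```

Read: in the diseased condition, 360 of 919 macrophages had this venous EC
subtype as their nearest EC where chance (its 11.9% share of ECs) predicts
~109 — a proximity score of 3.29, exact binomial *P* ≈ 1e-98. In the
non-ischemic condition the score is ~1 and the test is null, reproducing the
qualitative pattern the method is designed to detect. Label transfer on
these well-separated synthetic clusters recovers 100% of ground-truth
labels. All output tables, along with a manifest recording the
configuration, seed and row counts, are written to `proxiscore_out/`.

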