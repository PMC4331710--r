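# iiinet

Most protein–protein interaction (PPI) resources record interactions at the
*gene* level, yet alternative splicing means a gene's transcript isoforms can
carry different protein domains and therefore different binding partners
(Bcl-xL binds BAK1; the short splice form Bcl-xS does not). `iiinet` is an R
package for researchers in network and systems biology who want to refine a
gene-level PPI network to the resolution of **isoform–isoform interactions
(IIIs)** using only two widely available kinds of evidence: isoform-level
RNA-seq co-expression and domain–domain interaction (DDI) annotations.

## The model

For every isoform pair (i, j) whose genes have a known PPI (the
PPI-confirmation filter), the package assembles

- `DDI_ij ∈ {0, 1, 2, 3}` — the best domain–domain interaction hit across all
  cross pairs of the two isoforms' domains, scored by confidence
  (high = 3, medium = 2, low = 1, no hit = 0), and
- `E1_ij, …, EK_ij ∈ [0, 1]` — the absolute Pearson correlation of the two
  isoforms within each of K expression datasets (missing entries are masked
  and treated as "no evidence"),

and scores the pair with a logistic regression

```
logit(y_ij) = α₀ + α₁ E1_ij + ⋯ + α_K EK_ij + α_{K+1} DDI_ij
```

whose per-dataset coefficients let noisy datasets down-weight themselves. The
model is trained on a gold standard built from the data themselves: positives
(GSP) are isoform-specified PPI records plus the unique isoform pair of any
PPI between two single-isoform genes; negatives (GSN) pair a plasma-membrane
isoform with a nuclear isoform among the GSP-covered isoforms (dual-localized
isoforms excluded). Positives recorded strictly after a cutoff date (default
2012-01-01) form the held-out test set.

Predictions are tiered by logit score — `high` (score > 2.575), `low`
(score > 1.692), both configurable or re-derivable from a target precision on
the precision–recall curve — and every PPI additionally retains its
best-scoring pair (`rescued`), so each PPI yields at least one III. On the
resulting network, a deterministic greedy seed-and-extend procedure discovers
**overlapping dense modules** (size 3–30, density ≥ 0.7), whose functional
coherence is quantified by hypergeometric GO/pathway enrichment (BH-adjusted)
against size-matched randomly drawn modules.

A fully seeded synthetic-data generator emits all six pipeline inputs with
planted ground truth (true IIIs, clique modules, coherent annotations), so the
entire pipeline is testable end to end without downloads.

## Worked example

```r
library(iiinet)

world <- generate_world(synthetic_world_config(seed = 1L))
world_to_files(world, "demo_world")
report <- run_pipeline(iii_pipeline_config("demo_world", "demo_out", seed = 1L))
str(report$counts)
```

```
List of 14
 $ isoforms         : int 415
 $ genes            : int 200
 $ ppi_records      : int 300
 $ gsp_train        : int 77
 $ gsp_test         : int 19
 $ gsn              : int 455
 $ candidates       : int 1341
 $ predictions_total: int 337
 $ high             : int 206
 $ low              : int 25
 $ rescued          : int 106
 $ network_nodes    : int 316
 $ network_edges    : int 337
 $ modules          : int 6
```

The 300 gene-level PPIs expand to 1,341 candidate isoform pairs; after scoring
with the model fitted on 77 training positives vs 455 negatives, 206 pairs
clear the high-confidence threshold, 25 more clear the low threshold, and 106
PPIs whose best pair clears neither keep that pair as `rescued` — so all 300
PPIs are represented. On the 19 held-out test positives:

```r
report$operating_points
#>   tier threshold precision    recall
#> 1 high     2.575 0.7777778 0.3684211
#> 2  low     1.692 0.7777778 0.3684211

unlist(report$enrichment_rates)
#>             GO        pathway      random_GO random_pathway
#>      0.8333333      0.5000000      0.1666667      0.1666667
```

Five of the six discovered modules (83%) carry a significantly enriched GO
term versus 17% for size-matched random modules — the planted functional
signal is recovered. Individual predictions carry their full evidence:

```r
head(read_predictions("demo_out/predictions.tsv")[ , 1:6], 4)
#>   isoform_a isoform_b logit_score tier ddi_score    d1
#> 1   G0002.1   G0145.1       13.31 high         2 0.582
#> 2   G0002.1   G0145.2       12.62 high         0 0.560
#> 3   G0003.1   G0043.2        6.56 high         0 0.144
#> 4   G0003.1   G0048.1        9.89 high         0 0.649
```

A command-line wrapper covers the same flow:

```sh
Rscript inst/cli/iii.R simulate --out demo_world --seed 1
Rscript inst/cli/iii.R run-all --input demo_world --out demo_out --seed 1
```

## Package layout

- `R/data_io.R` — TSV dialects and validation for all six inputs and both
  outputs
- `R/features.R` — `abs_pearson()`, `ddi_score()`, `build_feature_vectors()`
- `R/gold_standard.R` — GSP/GSN construction and the timestamp split
- `R/iii_model.R` — ridge-stabilized IRLS logistic fit, PR curves, tiered
  prediction with rescue
- `R/module_discovery.R` — overlapping dense-module discovery and the
  randomized null
- `R/enrichment.R` — hypergeometric enrichment and enrichment rates
- `R/synthetic_data.R` — the seeded world generator
- `R/pipeline.R` — `run_pipeline()` and the CLI dispatcher
- `vignettes/iiinet-methods.Rmd` — the methods vignette (model, assumptions,
  numerical choices, limitations)
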