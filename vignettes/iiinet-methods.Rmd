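---
title: "iiinet: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{iiinet: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iiinet)
```

# The problem

Gene-level protein–protein interaction (PPI) catalogs hide which transcript
isoforms actually mediate a binding event, even though splice variants of the
same gene can differ in exactly the domains that drive binding. `iiinet`
predicts isoform–isoform interactions (IIIs) by integrating, for every
isoform pair of a known PPI, domain–domain interaction (DDI) evidence and
per-dataset RNA-seq co-expression through a logistic regression, then mines
the predicted network for overlapping dense modules and scores their
functional coherence.

# The model and its assumptions

For isoform pair $(i, j)$ the linear predictor is

$$\mathrm{logit}\, y_{ij} = \alpha_0 + \sum_{k=1}^{K} \alpha_k E^{(k)}_{ij}
  + \alpha_{K+1}\,\mathrm{DDI}_{ij}$$

where $E^{(k)}_{ij} = |\hat r^{(k)}_{ij}|$ is the absolute sample Pearson
correlation of the two isoforms' expression across the samples of dataset
$k$, and $\mathrm{DDI}_{ij} \in \{0,1,2,3\}$ is the best confidence level
(high/medium/low $\to$ 3/2/1, no hit $\to$ 0) over all cross pairs of the two
isoforms' domains, matched orderlessly against the DDI table.

Assumptions worth making explicit:

- **Co-expression is evidence of interaction propensity, sign-free.** Only
  the magnitude of correlation enters; anti-correlated partners count equally.
- **Datasets self-calibrate.** Each dataset gets its own coefficient, so an
  uninformative or noisy dataset is down-weighted by the fit rather than
  filtered beforehand.
- **Absent evidence is null evidence.** When an isoform is missing from a
  dataset, or has zero variance in it, the correlation is undefined; the
  entry is masked and imputed as 0 at model time. 0 is the feature value
  meaning "no co-expression support", which makes imputation conservative
  rather than optimistic. The mask is preserved and written to output so
  consumers can distinguish "measured 0" from "unmeasured".
- **The candidate universe is PPI-confirmed.** Only isoform cross products of
  known gene-level PPIs are scored. Filtering up front is equivalent to
  predicting everywhere and discarding non-PPI pairs, and is far cheaper.

# Gold standard

**Positives (GSP)** come from two rules: isoform pairs carried by
isoform-specified PPI records, and — because a PPI between two
single-isoform genes is already isoform-resolved — the unique isoform pair of
any such PPI. A pair produced by both rules keeps the `isoform_specified`
provenance. PPI records naming exactly one isoform are rejected as malformed:
a half-specified record supports neither rule.

**Train/test split.** A GSP pair goes to the test set iff the *earliest*
timestamp among its supporting records is strictly after the cutoff (default
2012-01-01; the boundary date itself trains). Earliest-record precedence
prevents a pair known before the cutoff from leaking into the test set via a
later re-report, and makes the split invariant to record order.

**Negatives (GSN)** pair a plasma-membrane-only isoform with a nucleus-only
isoform among the GSP-covered isoforms; isoforms carrying both labels are
excluded from both sides, other compartments are ignored, and exact GSP pairs
are removed. We deliberately do *not* exclude pairs whose genes share a PPI
beyond that: the contamination rate is small and the rule stays minimal. The
full GSN serves both training and evaluation; only positives are split by
timestamp (the localization-derived negatives carry no record dates, so a
timestamp split of the GSN would be fiction).

# Fitting and operating points

The fit is iteratively reweighted least squares on the Bernoulli
log-likelihood with a small ridge penalty (default $10^{-6}$) on the slopes
only. The ridge exists for numerical stability: gold standards of this shape
are frequently linearly separable, where the unpenalized MLE diverges.
Convergence is declared when the max-norm of the penalized score drops below
$10^{-8}$ (at most 100 iterations, with step halving on likelihood decrease);
non-convergence is an error that reports the final gradient norm, never a
silent result. Standard errors come from the observed information at the
optimum.

Tier thresholds default to 2.575 (high) and 1.692 (low) with *strict*
inequality — a score exactly at a threshold does not clear it. These stock
values reproduce a published operating pair (60%/40% precision on that
study's data); on any other data they are just defaults, and
`threshold_for_operating_point()` re-derives a threshold from a target
precision by scanning the precision–recall curve for the smallest qualifying
threshold (recall is non-increasing in the threshold, so smallest qualifying
= maximal recall). The PR curve uses thresholds $-\infty$ plus every distinct
score; at the top threshold no pair is predicted and precision is `NA`, never
silently 1. The **rescue rule** keeps each PPI's best-scoring pair (ties
broken by canonical pair order) even below the low threshold, so every PPI
retains at least one predicted III.

# Module discovery

The published clustering method referenced for module discovery is not
specified in our sources, so `discover_modules()` implements a documented
greedy stand-in, *inspired by* overlapping dense-subgraph clustering but not
claimed identical: every edge seeds a module in decreasing degree-sum order;
a module repeatedly absorbs the neighbor contributing the most internal edges
(for fixed size, density is monotone in that count; ties break
lexicographically) while density stays $\ge$ 0.7 and size $\le$ 30; grown
modules of size $\ge$ 3 are emitted unless their member set is a subset of an
earlier module. The procedure is fully deterministic — the `seed` argument is
accepted for interface uniformity and ignored. Two consequences to be aware
of: the greedy extension may ride density down to exactly the cutoff, so a
planted clique is typically recovered as a slightly larger superset module;
and overlap arises naturally because different seeds can grow across the same
nodes. Density is the undirected simple-graph density $2E/(n(n-1))$.

The null model (`randomize_modules()`) redraws each module's members
uniformly without replacement from the node universe, preserving the size
multiset exactly — the standard size-matched randomization for enrichment
comparisons.

# Enrichment

Per module and term we test the hypergeometric upper tail
$P(X \ge k)$ with $X \sim \mathrm{Hyp}(N, K, n)$, BH-adjusted within module
and namespace, significant at adjusted $p < 0.05$ by default. These three
conventions (test, correction, alpha) are the field's defaults and all
configurable. The universe defaults to the network's isoforms rather than the
whole catalog, so unobservable isoforms cannot inflate significance.
Annotations are accepted at isoform granularity; protein-level annotations
should be propagated to all isoforms of the gene upstream (the synthetic
generator does exactly this for its background terms), which makes module
enrichment an approximation wherever isoforms of one gene differ functionally.

# The synthetic world

`generate_world()` emits all six inputs with planted truth. What it emulates:

- **Genes and isoforms**: 200 genes, 1–4 isoforms each (mean ≈ 2), isoform
  domain compositions drawn from a pool of 80 domains.
- **Truth topology**: every one of the 300 gene-level PPIs is backed by at
  least one truly interacting isoform pair — the same premise that justifies
  the rescue rule — plus extra cross pairs at rate 0.2; planted clique
  modules (4 modules of 5–8 isoforms, on disjoint genes) are fully true.
- **Co-expression**: 19 datasets of 20 samples (matching the scale of the
  multi-experiment RNA-seq panel the method was designed around), generated
  from latent factors shared along an edge clique cover of the true
  interaction graph (one factor per planted clique, one per remaining edge).
  A pair sharing no structure has population correlation exactly zero.
  Loadings are sign-randomized, so the generator itself verifies that only
  $|r|$ matters. An isoform in $m$ structures can carry at most $0.95/m$ of
  its unit variance per factor, so a truly interacting pair attains
  $|r| = \sqrt{q_i q_j}$ with $q = \min(\rho, 0.95/m)$: the target
  $\rho = 0.8$ when both isoforms have one interaction structure, attenuated
  for hubs. This attenuation is not a free choice — a node cannot be
  0.8-correlated with several mutually independent partners and keep a valid
  correlation matrix — and is the closest feasible realization of the target.
- **DDI**: 60% of true pairs receive a supporting record with a
  high/medium/low mix of 0.3/0.4/0.3; background noise records cover ~1% of
  domain pairs with a low-skewed mix (0.1/0.3/0.6), reflecting that spurious
  predicted DDIs are rarely high-confidence.
- **Localization and annotation**: independent membrane (0.1) and nucleus
  (0.4) priors; each planted module gets a dedicated GO term (pathway term
  for every other module) covering 90% of its members, on top of gene-level
  background terms.

What it does **not** emulate: read-level RNA-seq noise and quantification
ambiguity between isoforms of a gene, zero-inflation of lowly expressed
transcripts, the GO DAG (terms are flat sets), correlated gold-standard
errors, and genome scale. A green end-to-end test therefore establishes that
the pipeline recovers planted signal of realistic shape and strength — not
that it would reach any particular precision on real 2013-era databases,
whose headline numbers depend on unavailable snapshots.

All randomness flows from the single mandatory seed via an RNG-state-
preserving wrapper, so generation is byte-reproducible and does not disturb
the caller's stream.

# Numerical and degenerate-input policy

- Pairs are everywhere canonicalized lexicographically; all containers store
  canonical order only, which makes symmetry structural rather than tested-in.
- `abs_pearson()` returns `NA` on zero variance (correlation undefined)
  rather than 0 or an error; lengths below 2 are contract violations.
- Written numerics use 17 significant digits, so prediction and module files
  round-trip losslessly through their readers.
- Empty prediction or module sets write header-only files with a warning.
- Homodimer PPIs are retained; their candidate pairs include isoform
  self-pairs, which are excluded from the interaction *network* (no
  self-loops) but not from prediction output.
- An expression matrix needs ≥ 2 samples (one sample defines no correlation)
  and non-negative values; duplicate isoform rows are rejected.

# Known limitations

- The fitted coefficients are only as good as the gold standard; with very
  small GSNs (few membrane/nucleus annotations) the fit degenerates, and the
  pipeline reports the class-imbalance counts rather than guessing.
- The module algorithm is a stand-in: results will differ from the original
  clustering implementation in the source study, by design and by
  declaration.
- Threshold defaults are data-bound; on new data they should be re-derived
  from a target precision.
- Isoform-resolution mapping between interaction databases and the transcript
  catalog is assumed resolved upstream; the package validates consistency but
  performs no accession mapping.
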