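---
title: "Prioritizing Mendelian genes from gene-level features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing Mendelian genes from gene-level features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelprio)
```

## The problem and the model

Known Mendelian genes (positives, e.g. from OMIM) make up roughly a quarter
of the evaluable human gene universe; the remaining genes are *unknown*,
not negative — some of them harbour undiscovered disease relationships.
`mendelprio` treats gene prioritization as a positive–unlabeled regression
problem on a block-structured feature matrix:

* two aggregate variant pathogenicity scores per gene (the mean of an
  upstream per-variant predictor over all possible missense substitutions,
  and over stop-gains at every residue),
* one binary membership column per pathway and per GO biological process,
  each block closed by a per-gene membership count column,
* a fixed-width protein language model embedding.

The pipeline's stages are (1) univariate feature screening, (2) boosted
regression under cross-validation, (3) empirical precision calibration, and
(4) an iterated training round for the unlabeled genes.

### Screening statistic

Each membership column is contrasted between positives (group 1, size
$n_1$) and unknowns (group 2, size $n_2$) by a Mann–Whitney z-score with
tie-corrected variance. Values are midranked (ties share the mean of the
rank positions they occupy), and with rank sum $T_1$,

$$U_1 = T_1 - \frac{n_1(n_1+1)}{2}, \qquad \mu_U = \frac{n_1 n_2}{2},$$
$$\sigma_{U,\mathrm{corr}} = \sqrt{\frac{n_1 n_2}{n(n-1)}
  \left(\frac{n^3-n}{12} - \sum_{i=1}^{k}\frac{t_i^3-t_i}{12}\right)},
  \qquad z_1 = \frac{U_1 - \mu_U}{\sigma_{U,\mathrm{corr}}},$$

with $t_i$ the sizes of the $k$ tie groups. Binary membership columns are
*all* ties, so the correction matters: without it the variance of a sparse
indicator would be grossly overstated and its z deflated.

Two conventions are fixed here deliberately. First, $U_1$ is the pairwise
*win count* of group 1 (ties counting one half), so a **positive $z_1$
always means Mendelian-enriched**; the alternative orientation (defining
$U_1$ by subtracting $T_1$ from its maximum) merely flips the sign and
makes enriched terms come out negative, which is hostile to reading ranked
term tables. Second, no continuity correction is applied — the statistic is
used as a ranking and screening device, not as a calibrated test, and
p-values derived from it are reported only for descriptive parity.

A column whose values are all identical has $\sigma_{U,\mathrm{corr}} = 0$;
its z is *defined* as 0 and flagged degenerate, so any positive screening
cutoff drops it — the right outcome for a constant feature.

### Screening policy

Only the pathway and GO blocks are screened; the two aggregate scores and
the embedding dimensions always pass through. The cutoff is **strict**
(`z1 > cutoff`, default 0.1): features tied at exactly the cutoff are
dropped. Count columns are treated as ordinary screenable features of their
block — the arithmetic of the reduced reference widths
(2 + 1,057 + 1,672 + 1,024 = 3,755) only works if the counts live inside
the screened blocks, so that is the convention adopted.

Screening is fit once on the full labelled set, before cross-validation.
This mirrors a single global feature reduction and keeps one z-table as a
first-class result (it doubles as the per-term importance ranking used by
the network statistics). The leakage this induces is limited — the screen
uses labels only through a rank statistic, and the default cutoff of 0.1
is so permissive that the kept set is nearly insensitive to single folds —
but users who want strict fold hygiene can screen inside their own
resampling loop using `screen_features()` directly on training subsets.

### Boosted regression

The scorer is a gradient-boosted regression-tree ensemble with
squared-error loss and the operating point `n_estimators = 1000`,
`max_depth = 6`, `learning_rate = 0.05`. The backend is xgboost with
histogram-based growth on a single thread, which makes fits deterministic
for a fixed configuration, and the ensemble is initialised at the mean
target (the classical gradient-boosting initialisation). Remaining backend
knobs (subsampling, regularisation) stay at their defaults and are recorded
in run manifests. Targets are 1.0 for positives and 0.0 for unknowns in
round one; predictions are *regression scores*, not probabilities, which is
why calibration comes next.

### Precision calibration and the iterated round

The calibration curve maps a raw-score threshold $S_0$ to the fraction of
known positives among genes scoring **at least** $S_0$. The inclusive
"at least" is a deliberate choice: a strict "greater than" leaves the
top-scoring gene's own precision undefined (empty denominator). With the
inclusive variant every gene has a defined predicted precision, and at the
minimal threshold the curve equals the overall prevalence $P/N$.

The iterated round replaces each unknown gene's target with its predicted
precision under the *composite out-of-fold* round-one scores (positives
stay at 1.0), then retrains **on the same fold assignment**, so the two
rounds are comparable gene-by-gene. Using the global composite rather than
per-fold curves follows from treating the combined held-out predictions as
one prediction set; per-fold calibration would re-introduce fold-level
noise into the targets. Whether round-one precision should come from
out-of-fold or refit-on-all predictions is genuinely open; out-of-fold is
used because refit-on-all precision is optimistically biased for the exact
genes being relabelled.

### Evaluation

AUC is computed in its rank-statistic form (probability that a random
positive outranks a random negative, ties half), identical to the
trapezoidal ROC area. AUPR is the step-wise precision–recall area with no
linear interpolation between points and tied scores handled as one block —
linear PR interpolation is known to overstate the area. The enrichment
factor at $k$ ranks genes by descending score with ties broken by ascending
gene id (so reports are reproducible byte-for-byte) and divides the top-$k$
positive fraction by prevalence; its ceiling $(\min(k,p)/k)/(p/n)$ is
exposed separately because reported EFs are only interpretable against it.

### Term-level network statistics

Interaction degrees are computed on the union of the confidence-filtered
networks (keep `score >= 500` for integer-scored STRING-like lists and
`>= 0.5` for real-valued HIPPIE-like lists — boundary inclusive, since
"cutoff" alone does not specify strictness; the choice is visible and
testable). Self-loops are removed and a pair present in both sources counts
once. Per term, the maximal member degree and minimal member LCA age class
(1 = oldest) are taken over members *with data*; terms with no covered
member are excluded from the respective correlation populations rather
than imputed.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| screening cutoff | 0.1 | z-score | permissive reduction; large feature cuts with minimal performance cost |
| `n_estimators` | 1000 | trees | standard operating point of the method |
| `max_depth` | 6 | levels | interactions among membership bits and scores |
| `learning_rate` | 0.05 | — | small steps at 1000 trees |
| folds | 10 | — | composite out-of-fold evaluation |
| `top_k` | 180 | genes | ~1% of a 17,858-gene universe |
| `min_precision` | 0.7 | precision | candidate-list cutoff |
| PPI cutoffs | 500 / 0.5 | score / confidence | conventional confidence filters |

## What the synthetic generator emulates — and what it does not

`simulate_mendelian_data()` produces every input the pipeline reads, with
planted signal whose strength was fixed a priori from the structure the
method is designed around:

* labels at prevalence 0.27 (positive count `floor(n·prev + 0.5)`);
* catalogs in which 10% of terms are *enriched*: positive genes' membership
  odds are multiplied by `enrich_odds = 6` over a base rate of 0.05;
* two aggregate-score columns drawn from a two-component Gaussian mixture
  whose per-column separation $\delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$
  targets a standalone AUC of 0.78 — the typical strength of an
  aggregate-score predictor on its own;
* embeddings with a modest per-dimension shift (0.1 over 64 dimensions,
  standalone AUC ≈ 0.7) so they help but do not dominate;
* a PPI network where positives receive extra partners
  (`degree_boost = 15` expected, before confidence filtering), and LCA ages
  shifted 8 classes older for positives.

Each component draws from its own seed substream, so changing one
component's parameters leaves the other draws bit-identical — useful for
ablation-style tests.

Two fixture-design notes. The age distribution is deliberately
**young-skewed** (class probability ∝ class²): with ~100 members per term,
a uniform age distribution drives every term's *minimum* LCA to 1 and the
z–LCA correlation degenerates to zero variance. Real human gene-age
distributions are in fact ancient-heavy; the skew here serves the
statistic, not realism. More generally the generator does **not** emulate:
realistic GO DAG structure (terms are independent, real annotations are
nested), realistic scale-free degree distributions (the planted model is
Poisson-ish), correlated feature blocks (in real data aggregate scores,
memberships and embeddings are mutually correlated), or hidden positives
among the unknowns (the PU aspect of real labels). Passing tests therefore
demonstrate that the machinery recovers planted structure of plausible
strength — not that real-data performance will match any particular number.

## Numerical choices and degenerate inputs

* Genes missing from a score table or embedding file are zero-filled and
  flagged ("absent = no evidence"), keeping the matrix dense and the gene
  universe intact.
* All-tied screening columns get z = 0 with a degenerate flag (dropped by
  any positive cutoff).
* Top-k and candidate-report ties break by ascending gene id.
* `precision_at()` is a step function; scores below every observed
  threshold map to the overall prevalence.
* Fold assignment shuffles genes once (seeded) and deals fold indices
  round-robin, so fold sizes differ by at most one; 17,858 genes give
  sizes {1785, 1786}.
* Catalog term order is first-appearance order, frozen into column order,
  so feature matrices are reproducible from the same files.

## Problem sizes used by the test suite

The default benchmark bundle is n = 2,000 genes, 200 pathways, 500 GO
terms and 64-dimensional embeddings; the full two-round pipeline on it
runs in a few minutes on one CPU and is exercised once, in the acceptance
suite. Unit and property tests use much smaller bundles (40–400 genes,
4–15 terms) and a reduced boosting configuration, and the type-I-control
check of the screen runs at 6 + 6 terms so that the expected number of
false keeps at z > 3 across the whole screen stays well below one — with
hundreds of terms, a handful of |z| > 3 excursions is the expected
behaviour of a null normal statistic rather than a screening failure.

## Known limitations

* The screening z is univariate; redundant or anti-correlated term
  combinations are invisible to it by construction.
* Global screening before cross-validation leaks label information into
  feature selection (see above for why this is tolerated and how to avoid
  it).
* Empirical precision treats unknowns as negatives, so predicted precision
  is a *lower bound* wherever unknowns include true positives — which is
  exactly the regime the method is designed for.
* The iterated round is capped at two rounds; further self-training risks
  confirmation feedback and is out of scope.
* Gene identifiers are opaque case-sensitive strings; no alias resolution
  is attempted, so all inputs must share one identifier namespace.
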