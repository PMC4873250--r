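---
title: "Two-tier classification of heat shock protein families from sequence composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier classification of heat shock protein families from sequence composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsptier)
```

## The problem and the model

Heat shock proteins (HSPs) are stress-induced molecular chaperones found in
every domain of life, conventionally split into six families named by
approximate molecular weight: HSP20 (small HSPs), HSP40 (J-proteins), HSP60
(chaperonins), HSP70, HSP90 and HSP100. Annotating them from primary
sequence alone is a practical need in proteome annotation, and a naive
multi-class family classifier answers the wrong question for an unknown
query: it assumes the query *is* an HSP. `hsptier` therefore uses a
two-tier schema. Tier 1 is a binary gate that separates HSPs from
everything else; only gate-positive sequences reach tier 2, where six
one-vs-rest binary models (each family positive against the union of the
other five) produce decision values that are resolved to a single family.

Sequences of arbitrary length are mapped to fixed-length percentage
vectors. The *discrete* composition of a sequence with $N$ residues is

$$\mathrm{comp}(i) = \frac{R_i}{N} \times 100, \qquad i = 1,\dots,20,$$

where $R_i$ counts residue type $i$. The *coupled* composition counts
ordered adjacent residue pairs (overlapping dipeptides): a sequence of
length $L$ contributes $L-1$ pairs, and each of the $20^2 = 400$ ordered
pairs $j$ gets

$$\mathrm{coupled}(j) = \frac{M_j}{L-1} \times 100 .$$

Both vectors sum to 100 per sequence and are passed to the classifier as
raw percentages, double precision, with no further standardization. The
source literature for this design does not pin down the coupling distance;
we fix it at 0 (adjacent pairs) — the 400-dimensional pattern length and
common usage of dipeptide composition support that reading — and expose a
`gap` parameter for experimentation. Non-canonical residues (B, J, O, U,
X, Z, `*`, gaps, digits) are dropped by the default sanitation policy
precisely so that these two dimensionalities hold exactly; a strict policy
that rejects instead is available.

## The classifier

Both tiers use the same primitive: a soft-margin kernel support vector
machine with linear, polynomial $(x \cdot y + 1)^d$ or RBF
$\exp(-g\lVert x-y\rVert^2)$ kernels, plus a *cost ratio* $j$ that
multiplies the box constraint of positive training examples — the standard
device for class imbalance when 6 families share 2k positives against a
much larger background. No maintained SVM solver is available in this
package's dependency budget, so the dual problem is solved in compiled
code by sequential minimal optimization with second-order working-set
selection, the algorithm used by LIBSVM. The stopping tolerance defaults
to the conventional $10^{-3}$; the solver is fully deterministic, so a
trained model is reproducible bit-for-bit from identical inputs. The test
suite cross-checks decision values against an independent SVC
implementation on small fixtures; the two agree to solver tolerance, as
they must, since the C-SVC dual has a unique decision function.

Hyper-parameters are deliberately *not* hard-coded from published winning
values: solver internals, feature scaling and the unreported trade-off
constant $C$ do not transfer across implementations. Instead
`default_grid()` brackets the published vocabulary (polynomial degrees
1–5, gammas $5\times10^{-4}$–$10^{-1}$, cost ratios 1–40) and
`grid_search()` selects by pooled cross-validated accuracy, ties broken by
MCC, then grid order.

## Family resolution and its conventions

One-vs-rest stacks need a resolution rule, and the source design leaves it
unstated. We use argmax of raw decision values; exact ties break by
canonical family order (HSP20 < HSP40 < … < HSP100); and when every family
model rejects (all six values negative) we still report the argmax but
flag the verdict `low` confidence rather than refusing — deterministic,
and standard practice for one-vs-rest. The tier-1 threshold defaults to 0
and is configurable. A decision value exactly at a threshold classifies
positive; one convention, documented and tested.

## Evaluation machinery

Predictions are tallied into TP/TN/FP/FN — positive means "HSP" at tier 1
and "the family under test" at tier 2 — and summarized as sensitivity
$100\,\mathrm{TP}/(\mathrm{TP+FN})$, specificity
$100\,\mathrm{TN}/(\mathrm{TN+FP})$, accuracy, and the Matthews
correlation coefficient. Degenerate denominators are handled explicitly: a
sensitivity whose class is absent is `NA` with a warning (not silently 0),
and an MCC with a zero marginal is 0, the standard convention. ROC curves
sweep thresholds over distinct score values; AUC is the trapezoidal area,
which the tests verify equals the Mann–Whitney pair-counting statistic
with ties worth one half.

Cross-validation offers stratified five-fold (per-class fold counts within
±1 of perfect stratification, seeded shuffle) and leave-one-out ($n$
singleton folds). Fold results are *pooled* (micro-averaged) into one
confusion matrix before metrics are computed: the phrase "averaging the
results of all partitions" admits either pooling or macro-averaging, and
pooling is the only scheme that remains well-defined for leave-one-out,
where single-example folds have no per-fold metrics. The default workflow
configuration mirrors the published winning setup — coupled encoding,
five-fold at tier 1 (12k sequences), leave-one-out at tier 2 (small
per-family data).

## Enrichment analysis

To profile what distinguishes HSPs compositionally, `enrichment_test()`
computes, per residue, the fractional difference

$$\frac{X_{aa} - Y_{aa}}{Y_{aa}}$$

between pooled residue fractions of a query sample $X$ and a background
sample $Y$ — positive for enrichment, negative for depletion. $X_{aa}$ and
$Y_{aa}$ are pooled over all residues of each sample rather than averaged
per sequence; the sample-level phrasing of the statistic supports pooling,
and pooling is invariant under record duplication (a tested property). The
original analysis delegated significance to an external profiling service
whose test is undocumented, so significance here is a transparent seeded
bootstrap: sequences are resampled with replacement within each sample,
the statistic recomputed (default 10,000 replicates), and the replicate
distribution recentred at zero serves as the null spread for a two-sided
p-value with the $+1$ continuity correction. These p-values are honest but
are *not* expected to match the external tool's numbers. No
multiple-testing correction is applied by default (per-residue calls at
$p \le 0.05$ match the source convention); a Benjamini–Hochberg flag is
available. Group summaries use the conventional biochemistry classes
(positively charged K/R/H, negatively charged D/E, polar uncharged
S/T/N/Q/C/Y, hydrophobic A/V/L/I/M/F/W/G/P, aromatic F/W/Y/H); the
overlap (H, F, W, Y belong to two groups) is intentional and the lists
are overridable.

## The synthetic benchmark: what it emulates, and what it does not

Everything above is testable without downloads because
`make_benchmark()` generates labelled corpora from first-order Markov
chains over the 20-letter alphabet. First-order chains — not i.i.d.
residues — so that dipeptide structure exists for the coupled encoder to
exploit, mirroring the empirical finding that coupled features beat
discrete ones.

The default corpus shape is the real training corpus scaled down by 5:
71/256/33/57/12/17 sequences for HSP20…HSP100 plus 2,000 background
sequences, lengths uniform on [50, 400] (spanning small-HSP to HSP100
scale without claiming biological realism). Each family generator carries
a signature residue triple whose weights are multiplied by a separation
factor $s$ (strong 5, moderate 2.5, weak 1.4) and whose cyclic transitions
$r_1\!\to\!r_2\!\to\!r_3\!\to\!r_1$ are boosted by $s^2$. Crucially, the
six families are three triples × two cycle orientations: paired families
(e.g. HSP20/HSP40) share a stationary residue composition by symmetry and
differ only in dipeptide *order*. This bakes the qualitative structure of
the real problem into the stated world: the 20-dim encoder cannot fully
resolve the families, the 400-dim encoder can, so "coupled strictly
outperforms discrete" is a property of the generators, not a tuned
outcome. On the default strong benchmark with a held-out corpus, tier-1
accuracy and family accuracy are at or near 1.0 for the coupled encoding,
while discrete family accuracy drops to roughly 0.73 — the ordering the
acceptance suite asserts, direction only.

What a green benchmark does *not* establish: recovery of the performance
numbers reported for tools trained on real curated HSP corpora, which
require those corpora, their redundancy reduction, and the original
solvers' internals; nor realism of HSP domain
architecture — generators are statistical stand-ins with no homology
structure, so real-data performance claims must come from real data.

## Numerical choices and limitations

* SMO tolerance $10^{-3}$, iteration cap $\max(2\times10^5, 100n)$ with a
  warning (not an error) on cap — a near-converged model is still usable,
  and pure-noise label sets legitimately converge slowly.
* The full kernel matrix is held in memory: fine up to a few thousand
  training sequences (the intended scale); not suitable for $10^5$-scale
  corpora.
* Bundles are human-readable JSON with numbers at full double precision;
  round-trips preserve decision values to better than $10^{-10}$ (tested).
  The manifest's format version is the compatibility contract and
  mismatches are refused, not coerced.
* Duplicate FASTA ids are suffixed (`id`, `id_2`, …) with a warning rather
  than rejected, since proteome-scale scans commonly contain them.
* All stochastic steps (fold shuffles, chain sampling, bootstrap) take
  explicit integer seeds and restore the caller's RNG state.
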