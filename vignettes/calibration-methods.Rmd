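---
title: "Similarity-weighted calibration of docking scores: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-weighted calibration of docking scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockcal)
```

## The problem and the model

Docking scoring functions are calibrated globally, across many targets and
chemotypes, and consequently carry *systematic* error on any particular
target: whole chemical series dock consistently too strong or too weak. When
experimental Ki/Kd values exist for some ligands of the target, each such
reference ligand carries an empirical correction — the ratio between its
experimental binding free energy and its docking score. `dockcal` transfers
those corrections to query compounds in proportion to structural similarity:

$$DS_j = DS_j^0 \,\frac{1}{\omega}\sum_{i \ne j} S_{ij}^{\,p}\,
\frac{\Delta G_i}{DS_i}, \qquad
\omega = \sum_{i \ne j} S_{ij}^{\,p},$$

with $S_{ij}$ the Tanimoto coefficient between 2D fingerprints. The
correction factor is a convex combination of reference ratios (weights sum
to one), so the calibrated score always lies between the most extreme
rescalings the references propose — the method can redistribute trust but
cannot extrapolate beyond what the reference set supports.

The underlying assumption is the similarity property principle: structurally
similar molecules tend to share binding behaviour *and*, more specifically
here, to share the docking function's error. Activity cliffs violate the
first part; the method is robust to them to the extent that the error (not
the affinity) is what transfers.

## Parameters

* **`p` (CSE exponent, default 4, integer ≥ 1).** Controls how sharply
  weight concentrates on the most similar references. `p = 1` lets remote
  references dilute the correction; large `p` approaches a nearest-neighbour
  rule ($DS_j \to DS_j^0\,\Delta G_k/DS_k$ for the single most similar
  reference $k$ — a tested limit). The default 4 balances the docking signal
  against the similarity signal; values above 4 are accepted with a warning
  because the estimator degenerates toward a 1-nearest-neighbour lookup with
  its associated variance.
* **`tc_lower` (default 0, inclusive) / `tc_upper` (default none,
  exclusive).** Tanimoto window for contributing references. A lower bound
  alone is the focus-library scenario (lead optimisation); both bounds give
  the diverse-library scenario (lead identification), where
  `determine_tc_upper_bound()` sets the cap at the pooled median similarity
  between the test compounds and a general-purpose screening library — the
  smallest Tc below which more than half of screening-library similarities
  fall. The pooled-median reading was chosen over a per-test-compound
  statistic because it yields a single reproducible bound and the raw pooled
  distribution is attached to the return value so any alternative summary
  can be recomputed.
* **`min_references` (default 1) and fallback.** If fewer references survive
  the window, or all surviving weights are zero, the query keeps its original
  score and is flagged rather than erroring: on diverse libraries sparse
  neighbourhoods are normal, and a batch run must stay total.
* **`degenerate_score_epsilon` (default 0.1 kcal/mol).** References with
  docking scores above $-\epsilon$ are excluded: the ratio
  $\Delta G_i/DS_i$ is numerically unstable near zero and flips sign for
  positive scores. Weak-binder filtering (below) makes this rare in
  practice; query scores are deliberately *not* policed, since the formula
  rescales them linearly whatever their sign.
* **Affinity handling.** $\Delta G = RT\ln K_i[\mathrm{M}]$ at
  $T = 298.15$ K, $R = 8.314$ J mol$^{-1}$K$^{-1}$, reported in kcal/mol
  (1 kcal = 4184 J); Kd is treated identically to Ki. Replicate assay values
  aggregate by the arithmetic mean of Ki (not of pKi). Actives are
  compounds with aggregated Ki strictly below 100 nM by default — a cutoff
  tighter than the common 10 µM, chosen to balance active/inactive set sizes
  on potency-rich reference data; a compound exactly at the cutoff is
  inactive (the boundary had to be assigned somewhere, and the strict
  inequality is declared and tested). Weak binders with
  $\Delta G > -4$ kcal/mol (or $-5$ for Vina-style score scales) are removed
  before benchmarking so near-non-binders do not dominate error statistics.

## Fingerprints and similarity

FP2 (path-based, linear fragments of up to 7 heavy atoms hashed into 1024
bits), FP3 (55 SMARTS patterns), FP4 (307) and MACCS (166 structural keys)
are computed through OpenBabel via ChemmineR/ChemmineOB. OpenBabel pads the
SMARTS-based fingerprints to word multiples; the padding bits are provably
zero and are truncated to the canonical lengths. Molecules are canonicalised
on input (aromaticity perception, implicit hydrogens), so the same compound
read from SMILES or SDF produces identical bits — a tested invariant.
Externally computed bit vectors can be supplied as a hex table
(`read_fingerprints()`), which also makes the calibration engine
fingerprint-agnostic.

Tanimoto similarity of two all-zero vectors is defined as 1: the 0/0 case
arises only for featureless (or feature-free after truncation) molecules,
and treating them as maximally similar keeps $\omega$ finite instead of
propagating NaN into the weights. The case is logged when it occurs.

## Numerical and procedural choices

* Batch calibration computes the query-by-reference similarity matrix once
  and applies the formula as a masked matrix product; it is tested to agree
  *exactly* with a literal double-loop evaluation of the formula on random
  instances, including the Tc window, self-exclusion and fallback logic.
* Self-exclusion is by compound id only. A *different* compound with
  Tc = 1 to the query still contributes — identical twins are real
  information, whereas letting the query rescale itself by its own reference
  record would be leakage.
* Tc window: inclusive below, exclusive above. Raising the lower bound can
  only shrink the contributing set (a tested monotonicity).
* The predictive index is the Pearlman–Charifson pairwise statistic: pairs
  weighted by the experimental energy difference, sign credit for concordant
  order, zero credit for predicted ties. ROC AUC is the Mann–Whitney rank
  statistic with half-credit ties; the enrichment factor takes the top
  $m = \lceil f\,n\rceil$ by score with stable tie-breaking (warned when ties
  straddle the cutoff), with the count-based dialect as default and the
  retrieved-fraction dialect as an option. All three are verified against
  brute-force pair loops; AUC additionally against trapezoidal ROC
  integration.
* Repeated splits: reference:validation = 4:1 by default, ten repeats; each
  repeat draws its RNG stream from a Lehmer-style child seed
  $(48271\,s + r) \bmod (2^{31}-1)$, making every repeat independent yet the
  whole benchmark bit-for-bit reproducible. Ki-stratified sampling (levels
  split at 10 nM, 1 µM, 100 µM; at most 300 per level) balances the affinity
  distribution before splitting; by default the stratified draw is fixed and
  only the split is redrawn per repeat (a flag re-draws both).
* 95% confidence intervals over repeats use the normal approximation
  $\pm 1.96\,\mathrm{sd}/\sqrt{r}$ by default, with a Student-t option. With
  ten repeats the two differ visibly; the normal form is the default for
  comparability across grid cells.
* A validation split of a small library can end up single-class; the
  screening metrics are undefined there and reported `NA` for that repeat,
  and summaries aggregate over the defined repeats.

## What the synthetic generator emulates — and what it does not

`generate_compounds()` builds $k$ chemical series from distinct ring-system
scaffolds with enumerated small substituents, draws true binding energies
uniformly from $[-12, -5]$ kcal/mol per compound, and produces docking
scores as `slope·ΔG + intercept + cluster bias + noise`, with the bias drawn
once per cluster (sd 1.5 kcal/mol by default) and noise per compound (sd
0.5). This reproduces the two properties the calibration exploits: real
within-series fingerprint similarity (scaffold sharing, not simulated
similarity numbers) and series-correlated scoring error. The default size —
5 clusters of 20 — keeps a 4:1 split meaningful (80 references, 20
validation compounds) while the full benchmark stays in seconds.

It does **not** emulate: activity cliffs (energies are drawn independently
of structure within a cluster), realistic affinity–structure relationships,
3D conformational effects, or inter-series similarity gradients. Passing the
benchmark on this generator therefore demonstrates that the machinery
recovers series-level systematic error when it exists; it does not
demonstrate performance on real libraries, where the similarity–error
coupling is weaker and cliff-ridden.

In the designed regime (cluster bias ≫ noise) calibration at `p = 4`
improves RMSE and the predictive index in essentially every split, and the
improvement tends to grow with `p`; the per-split ordering across
`p = 1..4` is, however, noisy at 20 validation compounds, so monotonicity in
`p` should be read as a tendency of the means, not a per-split guarantee. In
the null regime (no cluster bias, identity score map) calibration leaves
RMSE essentially unchanged — it must not damage already-good scores — which
the test suite asserts as a median absolute RMSE shift below the noise sd.

## Known limitations

* The calibration never changes the *sign structure* of the correction: it
  rescales by a convex combination of reference ratios, so if every
  reference's docking score is wrong in a way unrelated to the query's
  error, the correction transfers noise. The method's own premise — similar
  compounds share scoring error — is load-bearing.
* FP2 here is OpenBabel's FP2; other toolkits' path fingerprints hash
  differently, and similarities from them should enter via the external
  fingerprint table rather than being assumed equal.
* The predictive-index and enrichment-factor conventions in the literature
  vary in detail (pair weights, rounding of the top fraction); the package
  fixes one convention each, documents it, and exposes the EF dialect as an
  option.
* Aggregating replicate Ki by arithmetic mean over-weights weak outliers
  relative to a pKi mean; it is used deliberately for consistency with
  common curation practice and can be replaced upstream by the caller.
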