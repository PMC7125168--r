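---
title: "Methods: machine-learning discovery on MEG wPLI connectomes"
author: "megml authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: machine-learning discovery on MEG wPLI connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megml)
```

## The problem and the data model

`megml` implements a biomarker-discovery workflow for two-group
classification from MEG functional connectomes. A connectome here is the
set of weighted phase lag index (wPLI) values over all unordered pairs of
the 90 regions of the AAL parcellation — 4005 "edges" — computed per
subject within one canonical frequency band (Theta 4–7 Hz, Alpha 8–14 Hz,
Beta 15–30 Hz, low gamma 30–80 Hz, high gamma 80–150 Hz). The unit of
analysis is therefore a subjects × 4005 matrix per band, with binary
labels (`case` vs `control`), and bands are processed fully independently.

wPLI is estimated from the imaginary part of the epoch-wise FFT
cross-spectrum pooled over epochs and in-band frequency bins,

$$\mathrm{wPLI} = \frac{\left|\sum_k \mathrm{Im}\, S_{xy,k}\right|}
                       {\sum_k \left|\mathrm{Im}\, S_{xy,k}\right|},$$

which lies in $[0,1]$, ignores amplitude, and is blind to zero-lag
(volume-conduction-like) coupling. When no imaginary cross-spectral mass
exists at all (e.g. two identical channels) the estimator is defined to
return 0 — the 0/0 case is read as "no lagged synchrony", which keeps
edge weights total and in range. The reference literature does not fix an
epoch length or spectral estimator for resting recordings; the package
uses plain per-epoch FFT cross-spectra, and its simulator defaults to
2-second epochs at 600 Hz (enough to resolve the high-gamma band).

## Pipeline stages

1. **Univariate screen.** Per-edge Welch two-sample t-tests (two-sided,
   unequal variances; group sizes 23/21 make pooled variance an
   unnecessary assumption), flagged at raw $p < 0.01$. Deliberately *no*
   multiple-testing correction: the screen is a variance-preserving
   pre-filter for the feature-selection machinery, not an inferential
   endpoint. BH-FDR is available behind a switch for reuse. Degenerate
   zero-variance edges report $t = 0, p = 1$; exact ties are labelled
   `increase` with a recorded tie flag so output is deterministic.
2. **Unsupervised structure.** Edge-wise z-scoring, two-way hierarchical
   clustering (Euclidean distance, Ward `ward.D2` linkage — the sources
   we follow name neither, and Ward gives compact two-group cuts for the
   $k = 2$ read-off), and PCA on the centred z-scored matrix. Component
   signs follow a fixed convention (largest-magnitude loading positive).
   Cluster–label agreement is reported as the narrative "misplaced
   subjects per label" count plus the adjusted Rand index. These stages
   are descriptive; they carry no inferential weight downstream.
3. **CV-SVM-rRF-FS.** Participants are split 80/20 stratified by class
   (largest-remainder rounding; 23 + 21 subjects give 35 train / 9 test
   with 5 case + 4 control held out). On the training set only, 10
   stratified folds are drawn; within each fold-training portion the
   univariate screen is *recomputed* (leakage-safe default; a config
   switch reproduces the screen-on-full-training variant) and recursive
   random-forest feature selection prunes the candidates: fit a
   1000-tree forest with unscaled permutation importance, drop the
   lowest 20%, repeat to a floor of 2 features, then select the path
   point with minimal out-of-bag error, resolving ties toward the
   smallest set. The consensus list keeps edges selected in at least 5
   of the 10 folds.
4. **Final SVM.** RBF kernel on the consensus edges (a support-vector
   count of 31 out of 35 training subjects in the reference results
   suggests a nonlinear boundary), features z-standardised with
   training statistics, hyperparameters from a small grid
   ($C \in \{0.1, 1, 10\}$, $\gamma \in \{1/p, 0.01, 0.1\}$) scored by
   stratified 10-fold CV accuracy; ties resolve to the first grid entry.
5. **Permutation test.** Labels are permuted within the training set
   $B = 99$ times; the model is refit (same edges, same chosen
   hyperparameters, same CV protocol) and the internal CV accuracy
   recomputed. $p = (1 + \#\{\text{null} \ge \text{observed}\})/(B+1)$,
   so the attainable floor is exactly 0.01.
6. **External evaluation.** The held-out 20% is scored once with the
   training standardisation; the ROC is traced over distinct decision
   values and AUC computed by the Mann–Whitney rank formulation with
   ties counted 0.5 (exactly the trapezoidal area of that ROC).
7. **PLS-DA verification.** An independent classifier on the same
   consensus edges: NIPALS PLS with the class coded ±1 and centred
   (decision by sign), 2 components, X standardised inside each CV fold.
   VIP scores are cumulative over both components,
   $VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\lVert w_a\rVert)^2 / \sum_a SSY_a}$
   with $SSY_a = b_a^2 t_a^\top t_a$, flagged at the 0.8 importance
   threshold; $\sum_j VIP_j^2 = p$ is an algebraic identity of this
   definition and is asserted on every fit. Per-component VIPs are
   exposed alongside the cumulative score.

Every stochastic stage derives its own seed from one top-level integer
via a documented rolling-hash derivation, so stages are independently
reproducible and a fixed seed and configuration reproduce every output
byte for byte.

## The synthetic-data generator

The study this framework targets deposited no raw data, so the package
ships a generator whose defaults emulate the study design: 23 case and
21 control subjects, 90 regions (4005 edges), the five canonical bands,
and per band a planted set of discriminative edges matching the
reference univariate profile — 30/40/49/22/59 edges with
increase/decrease splits 15/15, 22/18, 30/19, 7/15 and 26/33. Where the
sources state no value we fixed one once: default effect size
$d = 1.2$ SD (large enough that a screen at $p<0.01$ with $n=44$
recovers most planted edges, small enough that single edges are not
individually decisive), baseline edge weight 0.3 and between-subject SD
0.4 on the logit scale.

Two generation modes exist:

- **Direct-edge mode** (default test path): subject edge weights are
  drawn logit-normal around the baseline and the planted effect
  $d \cdot \sigma$ is added on the logit scale for cases only. The
  bounded inverse-logit keeps values in $(0,1)$ so an effect is never
  silently clipped away, and increase/decrease remain monotone.
- **Time-series mode** (validates the wPLI estimator itself): per
  subject, epoched signals in which each planted region pair shares a
  band-centre sinusoidal carrier injected at a fixed phase lag
  ($\pi/4$ by default; lags congruent to 0 mod $\pi$ are flagged since
  wPLI cannot see them), mixed with FIR band-passed noise. The carrier
  weight is the coupling strength: the control baseline (0.4) shifted
  by $0.15\,d$ in the planted direction for cases, clamped to $[0,1]$.
  Carrier phases are re-drawn per epoch, so only the lag structure is
  shared — which is exactly what wPLI measures. Planted pairs should be
  region-disjoint in this mode; overlapping pairs trigger a warning.

What the generator does *not* emulate: 1/f spectral structure, spatially
correlated noise between edges sharing a region, volume conduction,
subject-level covariates, or site/session effects. Passing tests on this
generator therefore demonstrate the statistical machinery — calibration,
leakage-freedom, recovery and ranking of genuinely discriminative edges
— not performance on real MEG data.

## Numerical choices and degenerate inputs

- Matrix symmetry tolerance $10^{-9}$; values outside $[0,1]$ by more
  than that are rejected, never clipped.
- Edge order is the row-wise upper triangle — pairs $(i,j)$, $i<j$,
  1-based, lexicographic — a pure function of the region list.
- Across-band "mean ± SD" of significant counts uses the sample SD
  ($n-1$): the reference counts 30/40/49/22/59 then give 40 ± 15
  (population SD would give 13). A single band reports SD 0 with an
  explicit flag.
- Zero significant edges, an empty consensus, or a constant edge are
  all explicit, typed outcomes (`empty_selection`, `no_signal`,
  tie flags) rather than errors or NaNs; a no-signal model evaluates at
  AUC 0.5 by construction.
- NIPALS runs to $10^{-10}$ or 500 iterations; with a single response
  it converges on the first pass, and non-convergence would be flagged,
  not ignored.
- Stratified folds are re-drawn with an incremented sub-seed if any
  training portion would lose a class.

## Design choices where the sources were open

- **Smallest-tie selection compresses signatures.** Selecting the
  elimination-path point with minimal OOB error and breaking ties
  toward fewer features means that when a few strong edges already
  separate the groups (OOB error 0), fold-level selections are 2–3
  edges. Consensus lists on strongly planted synthetic data are
  therefore compact, high-precision signatures: in our recovery
  simulations the selected set is a pure subset of the planted edges
  and the elimination path retains exactly the planted set at the
  matching path size, while exhaustive recall of every planted edge is
  *not* a goal of the rule. Classification performance is unaffected.
- **Permutation test at fixed hyperparameters.** The observed internal
  CV accuracy is a maximum over the small grid while null refits use
  the chosen configuration only. This is the usual practice and cheap,
  but mildly anti-conservative under the null; the package's
  calibration test therefore isolates the permutation machinery with a
  single-point grid, and users wanting strict calibration should pass a
  single-configuration grid.
- **Descriptive vs leakage-safe univariate arm.** The per-band
  Table-style summary is computed on the full sample (descriptive); the
  screen feeding feature selection is recomputed per fold inside the
  training set. Both scopes are available (`filter_scope`).
- **Consensus rule** is a frequency threshold (≥ 5/10), configurable;
  union and intersection are the `consensus_min = 1` and `= 10`
  extremes.

## Problem sizes used by the test-suite simulations

Monte-Carlo checks run at sizes chosen to keep the default suite quick
while preserving the tested property: type-I calibration pools 20 seeds
× 4005 null edges; the leakage guard runs 50 reduced pipelines (32
regions, 200 trees); consensus-recall monotonicity uses 10 seeds at 25
regions; permutation-null calibration 100 runs at $B = 19$ with 4
folds; the end-to-end external-AUC check runs 5 full-scale seeds
(4005 edges). The acceptance script reruns the full-scale analyses from
scratch at the emulated study size.

## Known limitations

- Bands are modelled independently; no multi-band fusion.
- The RBF-SVM grid is deliberately small; no Bayesian or continuous
  hyperparameter search.
- PLS-DA is two-class only; no sparse or orthogonalised variants.
- With 9 external test subjects the AUC has a coarse support; single-seed
  AUC values on synthetic data should be read with that granularity in
  mind.
- The generator's independence assumptions (edges i.i.d. given group)
  make the synthetic task easier than real connectomes with correlated
  edges; external AUC on real data will generally be lower at equal
  effect size.
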