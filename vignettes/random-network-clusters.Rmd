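---
title: "Random neural network clusters for connectome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random neural network clusters for connectome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnncluster)
```

## The problem and the method

Resting-state functional connectivity summarizes a brain scan as one
Pearson correlation per pair of atlas regions. With the standard 90-region
AAL parcellation that is 4005 edge features per subject, against cohorts
of a few dozen subjects — a regime where any single classifier overfits
and where classical dimension reduction (PCA and relatives) discards the
interpretable edge identities that clinicians care about.

The *random neural network cluster* attacks both problems with a
random-subspace ensemble:

1. Split the cohort into training and test sets (8:2 by default; 61
   subjects give 48/13 under the floor rule).
2. Repeat `k` times (default 1000): draw `n` subjects (default 45) from
   the training set and `m` features (default 120) from the universe,
   both uniformly without replacement, and fit a neural classifier on
   that subset.
3. The ensemble predicts a new subject by majority vote over the `k`
   learners; its accuracy is the fraction `C/N2` of correctly labelled
   test subjects.
4. Learners whose individual test accuracy exceeds a threshold (strictly
   greater than 0.6) are *significant*; counting how many significant
   learners drew each feature ranks the edges. The top-ranked edges
   (240 by default) are candidate markers.
5. A scan over candidate feature-set sizes (140 to 240 in steps of 10 —
   11 clusters, each built from a pool restricted to the top `c` edges)
   picks the count with the highest ensemble accuracy, ties resolving to
   the smallest count.
6. Each selected edge touches two regions; a region's *weight* is the
   number of selected edges incident to it. Heavy regions are the
   candidate abnormal regions for the group contrast, and the weight
   table exports directly to BrainNet Viewer `.node`/`.edge` files.

Labels are `+1` for the control group and `-1` for the case group
throughout. A tied vote (possible because `k` is even in the default
configuration) resolves deterministically to `+1` rather than by coin
flip, so repeated runs are bit-for-bit reproducible.

## Base learners

The ensemble treats its base classifier as a plug-in contract
(`fit(x, y, params)` / `predict(model, x)`). The default kind, `"mlp"`,
is a one-hidden-layer feed-forward network (via `nnet`): 10 hidden
units, cross-entropy objective, weight decay 0.1, at most 100 training
epochs, with per-feature standardization fitted on each learner's own
training rows. Decay matters here: each learner sees ~120 features and
only ~45 subjects, and an unregularized network of this size memorizes
noise. A `"ridge"` kind (penalized logistic regression via `glmnet`)
provides a fast linear reference, and any object with `fit`/`predict`
functions slots in — the historical method compared five neural network
variants, which is exactly the role of this contract. Non-convergence
within the epoch budget is not an error; the partially trained network
simply votes like any other learner.

## Randomness and reproducibility

One master seed drives everything. Substream seeds are derived from it
(one for the split, one per learner covering both its subset draw and
its weight initialization, one for the scan), so no stage's results
depend on how much randomness another stage consumed. The scan reuses
the *same* per-learner substreams for every candidate count, so scan
candidates differ only by their feature pool. Subject draws that land in
a single class are rejected and redrawn (at most 100 attempts) — an
untrainable one-class learner is never silently produced.

## The synthetic cohort generator

There is no public reference dataset bundled with the package; instead
`simulate_cohort()` generates cohorts with a known ground truth. Each
subject's regional series is `T` independent multivariate-normal draws
(default `T = 130`, a typical resting-state scan length after dropping
initial volumes) whose correlation matrix is `base_r` (default 0.1)
everywhere, except that a chosen set of *planted* edges (default 20) is
raised to `base_r + delta` (default `delta = 0.4`) in the case group.
Group sizes default to 36 controls / 25 cases, mirroring a 61-subject
clinical cohort. If the raised target matrix is not positive
semi-definite it is repaired by eigenvalue clipping and re-normalization
to unit diagonal; a repair that moves any planted correlation by more
than `delta/4` aborts, because the requested signal is then not
realizable as a correlation structure.

`noise_sd` (default 0.1) adds white observation noise on the series and,
in the fast path `simulate_feature_matrix()` that emits edge features
directly, is the feature-level noise. The default was set once to match
the sampling error of a Pearson correlation at `T ~ 130` timepoints
(roughly `1/sqrt(T - 3) ~ 0.09`), so the fast generator produces features
about as noisy as correlations estimated from the slow one.

What the generator deliberately does *not* model: temporal
autocorrelation, hemodynamics, subject motion, scanner drift, or
spatially structured noise. Passing tests on this generator therefore
demonstrates that the machinery — splitting, subspace sampling, voting,
thresholded counting, scanning, region weighting — behaves as specified,
not that the method will reach any particular accuracy on real scans.

## When frequency counting can and cannot find the planted edges

The feature ranking is a counting statistic, and its resolving power is
a matter of arithmetic worth stating explicitly. A planted edge is drawn
by `Binomial(k, m/M)` learners — mean `k*m/M`. Background edges
accumulate counts at rate `m/M` per significant learner. Selection
therefore separates planted from background edges only when (a) the
accuracy threshold admits mostly planted-containing learners, and (b)
`k*m/M` clears the upper tail of the background count distribution
across all `M` features. With `M = 4005`, `m = 120` and `k = 200`, a
planted edge is drawn by only ~6 learners (sd ~2.4) while the top-40
cutoff among ~4000 background features sits near count 8 — so desk-scale
clusters of 200 learners recover only a minority of planted edges
regardless of how strong the signal is, and reliable recovery on a
4005-edge universe needs on the order of 1000 learners. The test suite
demonstrates near-perfect recovery in a regime sized for the statistic
(435-edge universe, 5 planted edges, `k = 400`, threshold 0.7, expected
planted count ~18), and the acceptance checks report the measured
recovery under the default desk-scale conditions as-is.

## Numerical and degenerate-input choices

* Correlations are raw Pearson `r`; no Fisher transform.
* A constant regional time series makes the correlation undefined; it is
  a hard error naming the region, never a silent `NaN` or zero.
* Frequency ties rank by ascending edge index; scan-accuracy ties pick
  the smallest count; vote ties pick `+1`. All ties are deterministic.
* Feature standardization gives zero-variance features unit scale, so a
  constant-feature learner degrades to predicting its majority class.
* An empty significant-learner set aborts the pipeline with guidance to
  lower the threshold, since every downstream stage would be vacuous.
* Per-learner evaluation uses the held-out test set by default, which
  matches the reference protocol but leaks test labels into feature
  selection; `evaluation = "oob"` scores each learner on the training
  subjects it never drew instead. The faithful mode stays the default
  and the leakage is a documented limitation.

## Problem sizes used by the checks

The bundled tests and the acceptance script run at desk scale on one
CPU: unit tests use cohorts of 24–61 subjects over 6–30 regions with
clusters of 20–400 learners; the acceptance computations use the default
61-subject, 90-region cohort with 200-learner clusters, 100 learners per
scan candidate, recovery averaged over 3 seeds and ensemble-dominance
gaps over 5 seeds. These sizes are the package's chosen demonstration
scale; the defaults (`k = 1000`) remain those of the full protocol.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(R = 20, T = 100, n_pos = 30, n_neg = 24,
                        planted = 6, delta = 0.5, seed = 1)
D <- build_feature_matrix(simulate_cohort(cfg))

cc <- cluster_config(k = 200, n_samples = 40, m_features = 20,
                     top_n = 60, scan_counts = seq(20, 60, 10),
                     scan_k = 100, seed = 1)
res <- run_full_pipeline(D, cc, atlas = synthetic_atlas(20))
res
mean(planted_edges(D) %in% res$selected_features)
head(filter_regions(res$region_weights, 0))
```

## Known limitations

* The default evaluation protocol reuses one small test set for learner
  significance, feature scanning and the final accuracy; the reported
  accuracy is therefore optimistically biased. Out-of-bag evaluation
  mitigates but does not remove this.
* Binary `±1` classification only.
* The generator's multivariate-normal series have no temporal structure;
  effective sample sizes on real autocorrelated scans are smaller than
  `T` suggests.
* Exact replication of legacy neural-network toolbox variants (Elman,
  probabilistic, learning-vector-quantization, competitive networks) is
  out of scope; the learner contract is the extension point.
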