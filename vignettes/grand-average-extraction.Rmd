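---
title: "Extracting grand-average connectivity networks by non-negative parallel factorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting grand-average connectivity networks by non-negative parallel factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netparafac)
```

## The problem

Group studies of directed functional brain connectivity produce one
network per subject — typically a $K \times K$ matrix of partial directed
coherence (PDC) values estimated from multichannel EEG — and ask what
pattern the *group* shares. Averaging binarized networks cell by cell, or
running a statistical test per connection with a family-wise correction,
either blurs the pattern or prunes it to near-emptiness as $K$ grows.
This package implements an alternative: stack the vectorized subject
networks into a non-negative matrix
$X = [\pi^{(1)} \; \pi^{(2)} \cdots \pi^{(S)}] \in \mathbb{R}^{K^2\times S}$
and factorize it as a sum of $f$ non-negative rank-one terms,

$$X \approx \sum_{r=1}^{f} a^{(r)} \otimes b^{(r)},
\qquad a^{(r)} \ge 0,\; b^{(r)} \ge 0,$$

minimizing the **entrywise L1 norm** of the residual rather than the
Frobenius norm. Each $a^{(r)}$ is a candidate connectivity pattern; the
loading vector $b^{(r)}$ says how strongly each subject expresses it. A
pattern genuinely shared by the group should be expressed about equally
by everyone, so the component whose loading column has **minimum
variance across subjects** is taken as the grand average. The L1 loss is
preferred because it yields sparse reconstructions, which match the
structure of thresholded connectivity matrices better than the dense
least-squares fit.

The factor count is bounded by $f \le \mathrm{rank}(X) \le S$: you can
never ask for more patterns than there are subjects.

## From time series to subject networks

Subject networks are estimated with squared PDC. A multivariate
autoregressive (MVAR) model
$Y(t) = \sum_{p=1}^{P} A_p\, Y(t-p) + \varepsilon(t)$ is fitted by
ordinary least squares over lag-embedded rows stacked across trials (no
lag crosses a trial boundary), with the order $P$ chosen by AIC
($N\,\ln\det\hat\Sigma + 2PK^2$, all candidates fitted on the same
regression rows so the likelihood terms are comparable). The spectral
transfer matrix is

$$\Lambda_{ij}(f) \;=\; \delta_{ij} - \sum_{p=1}^{P} a_{ij}(p)\,
  e^{-\mathrm{i}\,2\pi (f/f_s)\, p},$$

with the frequency normalized by the sampling rate, and squared PDC is
the column-normalized magnitude
$\pi_{ij}(f) = |\Lambda_{ij}(f)|^2 / \sum_m |\Lambda_{mj}(f)|^2$, so that
entry $(i,j)$ measures the directed influence $j \to i$ and every column
of every frequency slice sums to one. Note the sign convention: the
coefficient matrices stored in an `mvar_model` are the conventional AR
matrices $A_p$ of the equation above (a formulation that moves all terms
to one side with $\lambda(0)=I$ stores their negatives; the transfer
matrix is identical).

Band networks (θ 3–7 Hz, α 8–12 Hz, β 13–30 Hz, γ 31–40 Hz by default)
are arithmetic means over in-band bins of an integer-Hz grid capped at
40 Hz. Binarization against the no-coupling null uses per-connection
thresholds from **phase-randomized surrogates**: each channel of each
trial gets an independent random phase spectrum (preserving its
amplitude spectrum, destroying cross-channel coupling), the full
statistic is recomputed per surrogate, and the $(1-\alpha)$ empirical
quantile thresholds each connection (defaults: $\alpha = 0.05$, 100
surrogates). Asymptotic-theory thresholds can be substituted through the
`threshold_fn` argument. Since adjacent electrodes share volume-conducted
signal, `spatial_filter()` removes connections between grid 8-neighbours
of the montage — except between the two sagittal lines flanking the
midline, which span the inter-hemispheric divide; the 24-electrode
sensorimotor montage (rows FC, C, CP, P × lines 5, 3, 1, 2, 4, 6) ships
as data (JSON) so other layouts can be supplied.

## The L1 solver

The L1 objective is non-smooth and the non-negativity constraint makes
the problem non-convex, so the solver matters. Both implemented variants
are iteratively reweighted schemes: each sweep majorizes the L1 loss by
a weighted quadratic with IRLS weights $w_{ij} = 1/\max(|x_{ij} -
\hat{x}_{ij}|, \varepsilon)$, $\varepsilon = 10^{-8}$, and minimizes it
over one factor matrix at a time.

* **`method = "mu"` (default)** applies the multiplicative update of the
  weighted quadratic (the Lee–Seung form generalized with IRLS weights).
  Iterates stay strictly positive, so a weakly-expressed component is
  attenuated but never annihilated. This matters scientifically: when
  $f$ approaches the number of subjects, the decomposition becomes
  non-unique and the shared pattern splits across components; strictly
  positive iterates keep every true connection weakly present in the
  selected component, which is what makes the extractor's miss rate
  (FNR) essentially independent of the factor count.
* **`method = "irls"`** solves each row's weighted least-squares problem
  exactly (Cholesky on the small $f \times f$ normal matrix, tiny ridge
  for degenerate rows) and clips negatives to zero. It reaches lower
  objective values and exact zeros — attractive as pure optimization —
  but the exact zeros eliminate weakly shared connections outright,
  which measurably inflates the miss rate on noisy groups. It is kept as
  an option and used in tests as a second route to the same optima on
  exactly-factorable inputs.

Neither reweighted step is monotone for the L1 objective itself, so the
solver tracks the best iterate seen and returns it; the reported
objective therefore never exceeds the value at initialization, and is
bounded by the all-zeros model's objective $\|X\|_1$.

Remaining numerical choices, fixed once and exposed as arguments:

* **Initialization.** `n_init = 5` restarts; the first is a
  deterministic-given-seed warm start with every column of $A$ seeded at
  the jittered row mean of $X$ (the exact solution when all subjects are
  identical, and the common-mode basin in general), the rest are
  uniform(0,1). Best final objective wins; a restart that already fits
  (almost) exactly short-circuits the rest.
* **Stopping.** Relative objective change below `tol = 1e-6` or
  `max_iter = 500` sweeps, whichever first, plus a stall guard (50
  sweeps without improving on the best iterate).
* **Scale indeterminacy.** Each rank-one term leaves a positive scale
  free between $a^{(r)}$ and $b^{(r)}$. After fitting, every $a^{(r)}$
  is rescaled to unit L1 norm with the scale absorbed into $b^{(r)}$, so
  loading columns are commensurable and the variance comparison across
  factors is meaningful. Identically zero ("dead") factors are kept but
  flagged and excluded from selection; ties in the minimum variance
  break toward the lower factor index.

## Binarization scale

The selected pattern is thresholded at 0.001 by default. The threshold
is applied to the pattern expressed on the **average-subject scale**,
$a^{(r)} \cdot \overline{b^{(r)}}$, i.e. the rank-one term's typical
contribution to one subject's network. This keeps the threshold in the
units of the input networks (PDC values, or 0/1 for binarized inputs)
and independent of the node count. The alternative of thresholding the
unit-L1-normalized $a^{(r)}$ directly (available as
`threshold_scale = "unit"`) couples the effective threshold to $K$: a
uniformly weighted pattern of $E$ connections has entries $1/E$, which
for a 50-node network of density 0.1 is only four times the threshold,
so ordinary solver unevenness starts deleting true connections as $K$
grows. Surviving connections are finally re-assigned the mean value of
that connection across the subject stack ("mean-value substitution"),
and the diagonal is forced to zero — self-connections are excluded
throughout the package.

## The synthetic benchmark

`generate_dataset()` emulates a group study in which every subject
shares one underlying directed network up to random displacement of
connections:

* a ground truth with exactly $\mathrm{round}(0.1 \cdot K(K-1))$ edges
  placed uniformly among off-diagonal cells (density 0.1 over ordered
  node pairs, the convention used consistently for edge counts);
* per subject, a fraction $m$ of the edges (rounded half away from zero)
  is removed uniformly and the same number of new edges placed uniformly
  among the cells that are empty in the ground truth, so every subject
  has exactly the ground-truth edge count and shares exactly
  $E - \mathrm{round}(mE)$ edges with it;
* all randomness derives from one dataset seed through a drawn seed
  table, so datasets are bit-reproducible and subjects independent.

The study grids follow the benchmark design: $K \in \{20, 30, 50\}$
nodes, $S \in \{10, 20, 30, 50, 100\}$ subjects, swap fractions
$m \in \{0.1, 0.3, 0.5\}$, factor counts $f \in \{2, 5, 10\}$. Within a
simulation iteration one dataset is generated and factorized at every
$f$ (the factor count is an analysis choice, not part of the data).
Recovery is scored over off-diagonal cells only: FPR $= FP/(FP+TN)$ and
FNR $= FN/(TP+FN)$ on the binarized pattern, and the Mann–Whitney AUC
(ties counted half) of the selected factor's *continuous* weights
against the ground-truth labels — binarization would waste the ranking
information a ROC curve needs.

What the generator deliberately does **not** emulate: weighted
connectivity values, structured (modular or small-world) ground truths,
correlated noise across subjects, or inter-subject variability that is
not exchangeable displacement (e.g. subgroups using genuinely different
circuits). Passing the benchmark therefore shows that the extractor
recovers a shared pattern under exchangeable, density-preserving noise;
it does not certify behavior under systematic subgroup structure, where
a single grand average is the wrong summary to begin with.

```{r quick-example}
ds <- generate_dataset(K = 20, S = 10, m = 0.3, seed = 42)
ga <- extract_grand_average(stack_subjects(ds$subjects), f = 2, seed = 1)
cf <- confusion(ga$binary, ds$ground_truth)
c(FPR = fpr(cf), FNR = fnr(cf), AUC = auc(ga$scores, ds$ground_truth))
```

## Problem sizes used by the test suite

The shipped tests run the benchmark at desk scale: the full
$(S, m, f)$ grid at $K = 20$ with 50 iterations per cell, the
$S \in \{10, 20\}$, $f \in \{2, 10\}$ sub-grid with 100 iterations, and
single-iteration noiseless checks across all three node counts. The
acceptance script re-runs the $K = 20$ sub-grids at 100 iterations per
condition. Property tests (solver oracles, PDC normalization, surrogate
calibration) use small fixed-seed instances computed in code; nothing is
read from stored data files except the built-in montage.

## Known limitations

* The L1 solvers are local optimizers of a non-convex problem. Restarts
  and the warm start make the *selected grand average* highly
  reproducible, but the full factor set at $f$ near $\mathrm{rank}(X)$
  is not identifiable — different solvers (or tolerances) distribute the
  shared pattern across components differently, and quantities that
  depend on the *non-selected* components should not be interpreted.
* The multiplicative solver trades a somewhat higher final objective for
  strictly positive iterates; users wanting the sparsest attainable
  reconstruction should use `method = "irls"` and expect a higher miss
  rate on noisy groups.
* Surrogate-based binarization assumes the null of no cross-channel
  coupling is adequately represented by phase randomization; strongly
  non-stationary epochs violate this.
* MVAR/PDC estimation itself assumes linear, stationary dynamics within
  epochs, and the package deliberately contains no preprocessing
  (filtering, artifact removal, ICA): inputs are assumed clean.
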