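# netparafac

Group-level ("grand average") brain connectivity networks by
non-negative L1 parallel factorization, with squared partial directed
coherence (PDC) estimation from multichannel time series and a seeded
simulation benchmark for network recovery.

## Who this is for

Researchers with one directed connectivity matrix per subject — e.g. PDC
networks estimated from EEG during a motor task — who want the single
pattern the group shares, without the blurring of cell-wise averaging or
the extreme sparsity that per-connection testing with family-wise
correction imposes on large networks.

## The method

Each subject's K × K network is vectorized and the cohort stacked into a
non-negative matrix `X` (K² × S). `X` is factorized as a sum of `f`
non-negative rank-one terms,

    X ≈ Σ_r a(r) ⊗ b(r),   a(r) ≥ 0, b(r) ≥ 0,  f ≤ rank(X) ≤ S,

minimizing the **entrywise L1 norm** `Σ_ij |x_ij − Σ_r a_i(r) b_j(r)|`
(sparser reconstructions than the least-squares fit, which suits
thresholded connectivity data). Each `a(r)` is a candidate connectivity
pattern and `b(r)` its per-subject loadings; the component whose loading
column has **minimum variance across subjects** — the pattern expressed
most evenly by everyone — is the grand average. It is binarized at a
threshold (default 0.001 on the average-subject scale), and surviving
connections are re-assigned the mean value of that connection across the
cohort.

Upstream, subject networks can be estimated in-package: MVAR models
fitted by least squares across trials (AIC order selection), squared PDC
`π_ij(f) = |Λ_ij(f)|² / Σ_m |Λ_mj(f)|²` on an integer-Hz grid, band
averages (θ, α, β, γ), surrogate-null binarization, and a spatial filter
removing volume-conduction-suspect connections between adjacent
electrodes. Downstream, the classic least-squares PARAFAC/ALS for
third-order tensors and its building blocks (outer products, Khatri–Rao
product, matricization) are exported as well.

The solver is an iteratively reweighted scheme with two variants
(multiplicative updates, the default, and exact row-wise weighted least
squares with clipping); see the vignette
`vignettes/grand-average-extraction.Rmd` for the numerical design and
its rationale.

## Worked example

```r
library(netparafac)

# a synthetic cohort: 10 subjects sharing a 20-node network of density
# 0.1, each with 30% of its connections displaced
ds <- generate_dataset(K = 20, S = 10, m = 0.3, seed = 42)

ga <- extract_grand_average(stack_subjects(ds$subjects), f = 2, seed = 1)
ga
#> grand average: 20 nodes, 35 connections
#> selected factor 2 of 2 (loading variances: 10.2, 9.59)

cf <- confusion(ga$binary, ds$ground_truth)
round(c(FPR = fpr(cf), FNR = fnr(cf), AUC = auc(ga$scores, ds$ground_truth)), 4)
#>    FPR    FNR    AUC
#> 0.0000 0.0789 0.9940
```

The extractor selected the loading column with the smaller variance
(9.59), recovered 35 of the 38 planted connections with no false
positives (FPR 0), missed 3 (FNR 0.079), and the continuous factor
weights rank true connections above null cells almost perfectly
(AUC 0.994). `degrees(ga$binary)` summarizes each node's incoming,
outgoing and total connections; cell (i, j) is the influence j → i.

The same pipeline runs from the shell via the thin CLI in
`inst/cli/netparafac.R` (subcommands `simulate-data`, `simulate`,
`extract`, `pdc`, `degrees`).

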