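# hgimda

Heterogeneous graph inference for miRNA–disease association prediction.

miRNAs regulate gene expression post-transcriptionally, and their
dysregulation is implicated in many human diseases; experimentally verifying
which miRNA drives which disease is slow and expensive. `hgimda` prioritizes
candidate miRNA–disease pairs computationally, under the standard assumption
that functionally similar miRNAs tend to be involved in phenotypically
similar diseases. It is aimed at researchers who have a curated set of known
associations (e.g. an HMDD-style edge list) and want a ranked list of
plausible new ones — including for diseases or miRNAs that have *no* known
associations yet.

## The model

Let *A* be the binary `nm × nd` adjacency matrix of known associations. The
method builds a heterogeneous graph from four ingredients:

- **Disease semantic similarity** *SS* from the MeSH Category-C hierarchy:
  each disease *D* is a DAG of its ancestor terms; a node *d* contributes
  `DD(d) = 1` if `d = D`, else `max{Δ · DD(d′) : d′ ∈ children(d)}`, and

  `SS(i, j) = Σ_{t ∈ T(i) ∩ T(j)} (D_i(t) + D_j(t)) / (DV(i) + DV(j))`,

  with `DV(D) = Σ_{d ∈ T(D)} DD(d)`.
- **miRNA functional similarity** *FS*: precomputed MISIM-style scores,
  consumed as data (coverage may be partial).
- **Gaussian interaction-profile (GIP) kernel similarity** on both sides:
  `K(u, v) = exp(−γ ‖IP(u) − IP(v)‖²)` with bandwidth
  `γ = γ′ / mean(‖IP‖²)`, where the interaction profiles IP are the rows
  (miRNAs) and columns (diseases) of *A*.
- **Integration**: `SM = (KM + FS)/2` where FS is observed, else `KM`;
  `SD = (KD + SS)/2` where SS is observed, else `KD`. The kernel fallback is
  what lets the model score entities missing from the curated tables.

After symmetric normalization
`S(i,j) ← S(i,j) / √(Σ_l S(i,l) · Σ_l S(j,l))`, association scores are the
fixed point of the two-sided propagation

`P ← α · SM P SD + (1 − α) · A`,

iterated from `P = A` until the L1 change falls below `10⁻⁶`. The first
iteration is exactly the sum over all length-three paths
miRNA → similar miRNA → known association → similar disease; the fixed point
accumulates the whole geometric series of longer paths with decay α.

Evaluation follows leave-one-out cross-validation: each known association is
masked in turn, all similarity kernels and the propagation are recomputed on
the training matrix, and the held-out pair is ranked among all unknown pairs
(**global**) or among the unknown miRNAs of its disease (**local**). Rank
percentiles yield a ROC curve whose area equals the Mann–Whitney statistic.

## Worked example

Everything is runnable without downloads via the planted block-model
generator, which emulates the joint structure the method exploits:

```r
library(hgimda)
library(dplyr)

sim <- simulate_block_dataset(block_model_params(
  nm = 20, nd = 12, n_blocks = 2, seed = 7))
sim$assoc
#> <assoc_matrix> 20 miRNAs x 12 diseases, 50 known associations (density 0.2083)

fit <- hgimda_fit(sim$assoc, sim$fs, sim$ss)
glance(fit)
#> # A tibble: 1 × 7
#>   n_mirna n_disease n_known alpha      tol iterations converged
#> 1      20        12      50   0.4 0.000001         11 TRUE

tidy(fit) |> filter(known == 0) |> slice_max(score, n = 3)
#> # A tibble: 3 × 4
#>   mirna_id disease_id score known
#> 1 mir015   disease001 0.116     0
#> 2 mir013   disease009 0.109     0
#> 3 mir019   disease003 0.108     0

rec <- loocv(sim$assoc, sim$fs, sim$ss, mode = "global")
roc_points(rec)
#> <hgimda_roc> 79 points, AUC = 0.7552
```

The top `tidy()` rows are unknown pairs whose miRNA and disease sit in the
same planted block — exactly the associations the generator withheld by
chance. The LOOCV AUC of 0.76 on this small, noisy 20×12 instance rises
above 0.8 at the default generator size (60×40; see below). `autoplot()` on
the `hgimda_roc` object draws the ROC curve.

A command-line front end wraps the same functions
(`inst/cli/hgimda simulate|predict|loocv`); every run writes a JSON manifest
of its parameters so results can be reproduced bit-identically.

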