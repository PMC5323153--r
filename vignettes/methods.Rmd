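---
title: "Heterogeneous-graph inference for miRNA–disease association: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous-graph inference for miRNA–disease association: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgimda)
library(dplyr)
```

## The problem and the model

Known miRNA–disease associations form a sparse bipartite graph: of the
`nm × nd` possible pairs, only a few thousand are experimentally confirmed
in curated databases. The working hypothesis of this package — shared by a
family of network-based predictors — is that functionally similar miRNAs
associate with phenotypically similar diseases, so unknown associations can
be inferred by propagating the known ones through similarity networks on
both sides of the bipartite graph.

The score matrix `P` is the fixed point of

```
P <- alpha * SM %*% P %*% SD + (1 - alpha) * A
```

where `A` is the binary association matrix, and `SM` (miRNA side) and `SD`
(disease side) are integrated similarity networks, symmetrically normalized.
The single application of the map to `A` itself is the sum over all
length-three paths `miRNA → similar miRNA → known association → similar
disease` (`one_step_scores()`); iterating accumulates the full geometric
series of longer alternating paths, each damped by another factor of
`alpha`. Unlike a random walk with restart seeded from a disease's known
miRNAs, the prior here is the whole association matrix plus two similarity
networks, so diseases (or miRNAs) with *no* known associations still receive
informative scores through their similarity neighborhoods — that is the
practical selling point of the construction.

### Similarity ingredients

**Disease semantic similarity.** Each disease is placed in the MeSH
Category-C hierarchy by its dotted tree numbers; its DAG contains the
disease and every term owning a proper prefix of any of its tree numbers.
Contributions decay by the factor `delta` per step away from the disease
(maximum over paths when a node is reachable several ways), and the
similarity of two diseases is the contribution mass of their shared nodes
relative to their total semantic values. A term with several tree numbers
gets one DAG holding the union of its ancestor paths, so a shared ancestor
is counted once in the semantic value. Prefixes with no owning term are
skipped and the edge joins the nearest indexed ancestor: the similarity is
then computed on the observable part of the hierarchy rather than failing on
incomplete tables.

**GIP kernel similarity.** A Gaussian kernel on the rows (miRNAs) or columns
(diseases) of `A`, with bandwidth normalized by the mean squared profile
norm. The normalization makes the kernel scale-free with respect to dataset
density: doubling the average number of associations per entity halves the
effective bandwidth.

**Integration.** Where a curated functional (miRNA) or semantic (disease)
score exists, the integrated similarity is the plain average of that score
and the kernel; elsewhere the kernel stands alone. We read the disease-side
formula as using the *disease* kernel `KD` — its miRNA counterpart has the
wrong dimensions there, an evident typesetting slip in the source
formulation of this method family.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `delta` | semantic decay per DAG edge (unitless, (0,1)) | 0.5 | the convention of the DAG-based semantic measure this follows; halves an ancestor's weight per step |
| `gamma_prime_d`, `gamma_prime_m` | raw GIP bandwidths (unitless, > 0) | 1 | GIP-kernel literature convention; the profile-norm normalization does the dataset-specific scaling |
| `alpha` | propagation decay / restart weight, [0,1) | 0.4 | weights three-hop evidence at 0.4 per extra round trip; small enough to converge in ~15 iterations, large enough that multi-hop structure matters |
| `tol` | L1 convergence cutoff | 1e-6 | change below this is far under score differences that affect any ranking |
| `max_iter` | iteration cap | 10000 | safety net only; the contraction reaches `tol` in tens of iterations |

`alpha` is the one parameter with real leverage and no principled default —
the method family acknowledges its selection as unresolved. The fixed point
is well-defined for any `alpha < 1`; users scanning `alpha` should look at
LOOCV AUC, which `loocv()` makes cheap at synthetic scale.

## Numerical choices

- **Normalization.** `S(i,j) / sqrt(rowsum_i * rowsum_j)` on both networks.
  The normalized matrix is similar to the row-stochastic `D^-1 S`, so its
  spectral radius is at most 1 and the propagation map is a contraction with
  modulus `alpha`; this is the property the convergence claim rests on, and
  why we read the normalization denominator as row sums over the running
  index (a constant denominator would not bound the spectrum).
- **Initialization.** `P(0) = A`. Because the map is a contraction the fixed
  point is initialization-independent; starting at `A` is exact for
  `alpha = 0` and converges fastest in practice.
- **Convergence metric.** Elementwise L1 norm of the difference matrix,
  checked after each full update; on return the fixed-point residual is
  below `tol` (asserted in the test suite).
- **Oracles.** `closed_form_fixed_point()` solves the stationarity condition
  exactly via the Kronecker-flattened linear system; it exists purely as an
  independent check on the iteration (capped at a few thousand unknowns
  because the flattened system is dense). `one_step_scores()` is likewise
  checked against a literal four-level loop.
- **Ties and degenerate folds.** LOOCV ranks use average ranks, which makes
  the ROC area equal the tie-corrected Mann–Whitney statistic. A local fold
  whose disease has every other miRNA already associated has an empty
  negative set; its beaten-negative fraction is defined as 0. An all-zero
  training matrix cannot define a kernel bandwidth (division by the zero
  mean profile norm); `gip_bandwidth()` refuses, and the pipeline falls back
  to `gamma = gamma_prime` with a message so LOOCV edge folds stay
  well-defined without inventing similarity.
- **Ranking output.** `write_predictions()` breaks score ties by miRNA
  identifier so output files are deterministic.

## Leave-one-out protocol

The GIP kernels, the integration and the normalization are all functions of
`A`, so the default recomputes them inside every fold — reusing the
full-data kernel would leak the held-out edge into its own similarity
neighborhood. `reuse_kernels = TRUE` offers the leaky variant anyway,
clearly labelled, because it is several-fold cheaper and useful for
parameter exploration; the functional and semantic similarities do not
depend on `A` and are computed once outside the folds. Global mode ranks
the held-out pair against every unknown pair of the training matrix; local
mode against the unknown miRNAs of the held-out disease. Rank-percentile
thresholds make the two modes' ROC curves comparable despite candidate sets
that differ by orders of magnitude.

## The synthetic generator

`simulate_block_dataset()` plants `n_blocks` latent groups: matched
miRNA–disease groups associate with probability `p_in` (default 0.3) versus
`p_out` (0.02) otherwise, and both similarity networks are drawn around
`s_in` (0.8) within groups versus `s_out` (0.1) between, perturbed by
truncated-Gaussian noise (`sim_noise = 0.05`, one interpretable dispersion
knob that keeps scores in [0, 1]) with a `fs_coverage = 0.7` fraction of
miRNA pairs observed. Group assignment is round-robin rather than random so
block sizes are balanced and reproducible. The default 60×40×4-block shape
gives roughly 200 associations — large enough for stable LOOCV statistics,
small enough that the full recompute-per-fold protocol runs in seconds.
`simulate_dag_forest()` complements it with a MeSH-style tree-number table
(one tree per block, each root owned by a dedicated term) so the DAG
machinery is exercised end to end: same-block diseases share at least the
root ancestor, cross-block diseases share nothing and score exactly 0.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: the heavy-tailed degree distribution of
curated association databases (well-studied miRNAs accumulate records, and
the method is known to tilt toward them), the correlation structure of real
MISIM scores, block overlap, or diseases belonging to several MeSH
subtrees at once (the readers and DAG code support multiple tree numbers;
the generator assigns one per disease). Recovery of planted blocks shows the
machinery is wired correctly, not that field AUC values transfer.

```{r signal}
dataset <- simulate_block_dataset(block_model_params(seed = 1))
rec <- loocv(dataset$assoc, dataset$fs, dataset$ss, mode = "global")
roc_points(rec)
```

## Known limitations

- Disease-name matching between the association table and the MeSH table is
  exact string equality; no synonym resolution is attempted, and unmatched
  diseases silently take the pure-kernel branch (by design, but worth
  checking when coverage looks low).
- Dense matrices throughout: fine to a few thousand entities per side (the
  curated-database scale this targets is ~500 × ~400); beyond that the
  per-fold LOOCV recompute dominates.
- The functional-similarity reader symmetrizes single-direction records at
  read time and rejects conflicting duplicates; it does not attempt to
  reconcile near-duplicate scores.
- Evaluation is LOOCV-only by scope: no k-fold variant, no bootstrap
  confidence intervals on AUC.
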