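---
title: "Decomposing hybrid EEG-fMRI connectomes with stability-selected ICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing hybrid EEG-fMRI connectomes with stability-selected ICA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hemodynamic (fMRI) and electrophysiological (EEG) functional connectomes
measure statistical coupling between the same brain regions on very different
time scales, and it is not obvious which parts of their network organization
they share. `connica` implements a data-driven answer: stack every subject's
fMRI connectome next to each of their frequency-resolved EEG connectomes and
decompose the stack into a small number of *hybrid connectivity traits* —
edge patterns spanning both modalities — together with mixing weights that
say how strongly each (subject, frequency band) observation expresses each
trait. Two kinds of traits are of particular scientific interest: a
*frequency-general* trait, expressed roughly equally in all bands and
organized along the canonical intrinsic connectivity networks (ICNs), and a
*frequency-sensitive* trait, whose weights vary with band (typically
gamma-dominant) and whose EEG and fMRI edge patterns diverge.

## The model

Let $E = n(n-1)/2$ be the number of region pairs on an $n$-region
parcellation. For subject $s$ and band $b$, the hybrid observation is the
row vector

$$x_{sb} = [\,\mathrm{vec}(FC^{\mathrm{fMRI}}_s) \,\|\,
            \mathrm{vec}(FC^{\mathrm{EEG}}_{sb})\,] \in \mathbb{R}^{2E},$$

where the fMRI block is *repeated* across that subject's $B$ band rows. The
stacked matrix $X$ ($SB \times 2E$) is modeled, after column centering, as

$$X \approx W T,$$

with $T$ a $K \times 2E$ matrix of traits (rows, unit norm here) that are
statistically independent across edges, and $W$ the $SB \times K$ mixing
weights. Estimation is PCA variance reduction followed by fixed-point ICA
with the *edges* as samples, repeated hundreds of times from random
initializations; only components that recur across runs are kept.

### Connectome construction

* **fMRI**: Pearson correlation between regional BOLD time courses
  (`pearson_fc()`), range $[-1, 1]$.
* **EEG**: per epoch, each regional source signal is Hann-tapered and
  Fourier-transformed; cross-spectra are pooled over the bins of a band
  (delta 0.5–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–60 Hz) and
  normalized into a coherency. The magnitude of the imaginary part
  (`band_icoh()`) discards zero-lag coupling, the signature of volume
  conduction, and lies in $[0, 1]$.
* **Range harmonization**: because $[0,1]$ coherencies and $[-1,1]$
  correlations cannot be stacked directly, the EEG connectome is mapped to a
  correlation-like matrix by correlating rows $i$ and $j$ of the coherency
  matrix over the $n-2$ columns excluding the pair itself
  (`harmonize_eeg()`), a matching-index-style similarity.

Two estimator details are deliberate choices, exposed as flags:

* *Signed-then-absolute epoch averaging.* The signed imaginary coherency is
  averaged over epochs and the absolute value taken at the end. Under
  independence the null level then shrinks like $1/\sqrt{\text{epochs}}$,
  which is the behavior one wants from an estimator; taking the absolute
  value per epoch first (`abs_before_average = TRUE`) instead converges to a
  positive bias floor. Both respect the $[0,1]$ range.
* *Pair exclusion in harmonization.* Excluding columns $i$ and $j$ prevents
  the pair's own edge from inflating its row similarity;
  `exclude = "none"` is available for comparison.

### Dimensionality reduction and ICA

`pca_reduce()` column-centers $X$ and keeps the smallest number $P$ of
principal components whose cumulative explained variance reaches
`var_frac` (grid 0.75–0.90 in the standard sweep). `ica_decompose()` then
runs fixed-point negentropy-maximizing ICA (tanh contrast, symmetric
decorrelation, tolerance $10^{-6}$, at most 1000 iterations) in the retained
$P$-dimensional subspace with edges as samples, extracting `n_ics`
components (grid 5–20). Whitening spans the full retained subspace rather
than being re-reduced to `n_ics` dimensions, so the variance fraction and
the IC count remain genuinely separate free parameters; the cost is that
runs can converge to different local optima — which is precisely what the
stability selection exploits. Non-converged runs are flagged and dropped.

### Stability selection

The ICA is repeated `n_runs` times (500 by default) with per-run seeds
`base_seed + run`. Components of every run are matched one-to-one to a
reference run (the first converged run) greedily by largest absolute trait
correlation; a reference component is *re-found* in a run when both the
absolute trait correlation and the absolute mixing-weight correlation of its
match exceed 0.75. Components re-found in at least 75% of the converged runs
are robust; each is reported as the sign-aligned average of its matched
instances, renormalized to unit trait norm. The overall sign is fixed so
the mean mixing weight is positive, falling back — since weights estimated
from column-centered data have mean zero by construction — to making the
largest-magnitude trait entry positive, so a modular trait reports positive
within-module edges. Averaging (rather than picking an exemplar run) and
using converged runs as the occurrence denominator are package choices,
recorded here because reasonable alternatives exist.

### Characterizing components

* **ICC of mixing weights** (`icc_oneway()`): one-way random-effects
  ICC(1) $= (MS_B - MS_W)/(MS_B + (k-1) MS_W)$, with the one-way ANOVA F
  test. Grouping by subject treats bands as repeated ratings of a subject
  (high values = subject fingerprint); grouping by band is the transpose
  (high values = frequency tuning). ICC(1) may be negative.
* **Signed modularity** (`signed_modularity()`): the fixed-partition
  quality function that weights positive edges more than negative ones,
  $Q = \frac{1}{v^+}\sum_{ij}(w^+_{ij}-e^+_{ij})\delta_{M_iM_j} -
  \frac{1}{v^++v^-}\sum_{ij}(w^-_{ij}-e^-_{ij})\delta_{M_iM_j}$ with
  $e^\pm_{ij}=s^\pm_i s^\pm_j/v^\pm$, evaluated against a canonical
  region-to-network partition. Significance (`modularity_pvalue()`) comes
  from sign-stratified weight-preserving randomization: within each sign
  class the multiset of edge weights is reassigned by iterated rank matching
  against residual strength products, preserving weights exactly and nodal
  signed strengths approximately. The add-one estimator
  $p = (1+\#\{Q_0 \ge Q\})/(n_{\mathrm{iter}}+1)$ makes the 5,000-iteration
  floor $1/5001 < 0.0002$ exactly representable.
* **Edge correlations, motion, top edges**: `edge_correlation()` for
  cross-modal and cross-dataset comparisons, `motion_spearman()` (mid-rank
  ties) for head-motion associations, and `top_edges()` for 99th-percentile
  edge summaries with module-pair counts. The percentile uses
  linear-interpolation quantiles with a `>=` tie rule; because "strongest
  connections" can mean edge weight or endpoint nodal strength, both
  rankings are implemented (`mode = "edge"` is the default, documented
  rather than guessed).

### Cross-dataset parameter sweep

`sweep_parameters()` runs the whole decomposition over the
`var_frac` × `n_ics` grid on two datasets, matches robust components across
datasets by absolute trait correlation, and scores every cell by the mean
absolute correlation of the matched fMRI and EEG parts over the tracked
components (two by default). A tracked component a cell fails to match
contributes zero, and a cell where either dataset has no robust component
scores zero — the consistent-zero convention. The selected cell maximizes
this score, favoring parameters that reproduce *both* components across
independent datasets rather than one component very well.

## The synthetic-data generator

`example_ground_truth()` + `simulate_dataset()` generate datasets with known
answers: $K$ planted trait pairs (an fMRI and an EEG edge pattern each),
subject-by-band-by-trait mixing weights, and i.i.d. Gaussian edge noise.
The EEG vector of $(s,b)$ is $\sum_k w_{sbk}\,\mathrm{eeg}_k + \epsilon$;
the fMRI vector of $s$ uses the *band-mean* weight
$\sum_k \bar w_{s\cdot k}\,\mathrm{fmri}_k + \epsilon$, so the fMRI block is
constant across a subject's rows exactly as the repeated-fMRI stacking
requires. Values are trait weights, not correlations; an optional `clip`
flag truncates to $[-1,1]$ for realism tests.

The reference design (26 subjects, 5 bands, 60 regions, 6 modules, edge
noise 0.05 = 5% of the unit within-module weight) plants:

1. an **ICN-conform, frequency-general** trait: modular patterns in both
   modalities with graded per-module strengths
   ($2.2 \cdot 0.68^{m-1} + 0.2$), and subject-general mixing
   $w_{sb} = u_s \sim N(1, 0.10^2)$;
2. a **divergent, frequency-sensitive** trait: an fMRI contrast between two
   modules' within-edges, an EEG contrast between two disjoint sets of
   between-module edges, and mixing $w_{sb} = p_b + \epsilon_{sb}$ with the
   gamma-dominant profile $p = (0.1, 0.1, 0.15, 0.25, 0.6)$ and
   $\epsilon_{sb} \sim N(0, 0.05^2)$.

Three design constraints fixed these defaults:

* **Orthogonality.** The planted traits are mutually uncorrelated over
  edges, because the ICA model assumes independent sources; planting
  correlated sources makes exact recovery impossible by construction.
* **Identifiability.** A negentropy-seeking decomposition can only find a
  trait whose edge distribution is markedly non-Gaussian. Flat two-level
  modular patterns are close to a scaled Bernoulli mixture (excess kurtosis
  ≈ 1.5) and lose IC slots to chance directions; the graded-strength
  modular trait (excess kurtosis ≈ 9) and the sparse signed contrasts are
  reliably found.
* **Variance budget.** Effect sizes put roughly 69% of the total hybrid
  variance in the two planted directions together, so the 75%-variance PCA
  retains $P \approx 10$ components and the standard `n_ics = 5` is
  feasible. Mixing draws are standardized to their designed spread exactly
  (effect sizes are design parameters, not estimates); otherwise the
  sampling variability of a 26-subject effect-size estimate would move the
  leading variance fractions across the 75% threshold and make the retained
  dimension, and with it the whole experiment, seed-dependent.

## What the simulations do and do not show

Two structural facts about the hybrid stacking surface in the simulations
and are worth understanding before interpreting real-data results.

*Band-tuned weights cannot reach the fMRI block.* The fMRI half of a
subject's rows carries the band-*mean* of a trait's weights. For a
frequency-sensitive trait with small subject-level variability the band-mean
is nearly constant across subjects and is absorbed by column centering: the
recovered component faithfully reproduces the trait's EEG pattern and its
band-tuned weights, but its fMRI half is near zero (matched fMRI-pattern
correlations around 0.1–0.4, against ≈ 1.0 for its EEG pattern and weights).
Conversely, giving the trait enough subject-level weight variance to make
its fMRI pattern recoverable splits it into a *separate* stable component,
because the band-varying and band-averaged weight vectors are nearly
orthogonal. This is a property of the repeated-fMRI design, not of the
estimator.

*Repeated fMRI noise creates subject-fingerprint components.* Because each
subject's fMRI edge noise is drawn once and repeated across their band rows,
it forms genuine low-rank structure. Its leading directions are supported on
the fMRI half only — a half-zero, half-Gaussian profile with excess kurtosis
≈ 3 — so every ICA run finds the strongest of them, and stability selection
correctly reports them as robust *within* one dataset (the reference
conditions yield 4 robust components: the two planted traits plus two
fingerprint components). They do not, however, replicate across independent
datasets, so the cross-dataset sweep prunes them — which is exactly the role
the two-dataset comparison plays in the real analysis, where two to four
stable components per dataset reduce to two replicable ones.

The generator also deliberately omits several features of real data: no
hemodynamic convolution or volume conduction (connectomes are simulated
directly, not from time series), noise is i.i.d. across edges with no
spatial autocorrelation, and mixing weights are Gaussian. Passing the
recovery experiments therefore demonstrates the correctness of the
estimation machinery under its own model assumptions, not performance on
real recordings.

## Numerical choices and degenerate inputs

* Edge order is fixed row-major upper-triangle; `devectorize()` inverts it
  and rejects non-triangular lengths.
* PCA basis signs are fixed (largest-magnitude loading positive), making
  `pca_reduce()` deterministic; ICA seeds are `base_seed + run`, so whole
  pipelines reproduce bit-identically from one integer.
* Zero-variance regions (`pearson_fc`), constant harmonization rows
  (error, or `NaN` with a warning under `permissive = TRUE`), all-zero
  matrices in `signed_modularity`, a sign class with zero total weight
  (contributes 0), all-equal weights in `top_edges` (kept under `>=`,
  empty with a warning under `strict`), and `n_ics > P` (actionable error)
  are all handled explicitly.
* Problem sizes used by the test-suite experiments: the full study geometry
  (26 × 5 × 60, 100 ICA runs, 1,000 modularity nulls) for the end-to-end
  recovery experiment, a reduced 2 × 2 parameter grid with 50 runs per cell
  for the twin-dataset sweep, and 12–24-region fixtures elsewhere.

## Known limitations

* The harmonization makes EEG values correlation-like but changes their
  interpretation from coupling strengths to connection-profile similarity.
* The occurrence denominator counts converged runs; with low convergence
  rates the effective number of runs behind a component can be much smaller
  than `n_runs` (both counts are reported in the fit).
* Greedy reference-run matching is order-dependent in principle; for
  well-separated components it agrees with optimal assignment, and the
  order-invariance property is tested on clean runs only.
* `top_edges()`'s two ranking modes can select different edge sets; results
  should state which mode was used.
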