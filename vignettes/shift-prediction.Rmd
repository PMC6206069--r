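---
title: "Predicting NMR chemical shifts in molecular solids with multi-scale SOAP kernels"
author: "soapshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NMR chemical shifts in molecular solids with multi-scale SOAP kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Solid-state NMR resolves crystal structures by comparing experimentally
measured chemical shifts with shifts computed for candidate structures:
a candidate whose computed shifts agree with experiment to within the
method's confidence interval is accepted as the structure. The computed
reference values normally come from plane-wave DFT (GIPAW) shielding
calculations, which cost hours to days per crystal. `soapshift` implements
the machine-learning alternative: a kernel regression that predicts the
isotropic chemical shielding of every H, C, N or O atom in a periodic
organic crystal directly from its atomic neighborhood geometry, in seconds,
together with the curation and ranking protocol that makes the prediction
usable for NMR crystallography.

Because no electronic-structure code is bundled, the package also ships a
synthetic data module: random packed periodic "crystals" and a shielding
oracle with a controllable short-range/long-range structure. It produces
training labels with the one property that matters to the learning
machinery — a dominant local dependence plus a weaker long-ranged tail —
so every claim the package makes about its own correctness is testable
offline.

## The model

An atom's environment `X` is everything within a cutoff radius `r_c` of it,
periodic images included. The environment is represented as a smooth
neighbor density — one Gaussian of variance ς² per neighbor, one density
channel per element — and encoded by the SOAP power spectrum: the density
is expanded in an orthonormal radial basis times real spherical harmonics,
and the expansion coefficients are contracted over the angular index so the
resulting vector is exactly invariant under rotations, translations and
neighbor permutation. Descriptors are normalized to unit length, so the
similarity kernel

    k(X, X') = (p(X) . p(X'))^zeta

equals 1 for identical environments and lies in [0, 1] always.

The predicted shielding is the kernel-weighted sum over the training set,

    sigma(X) = sum_i alpha_i k(X, X_i),

with the weights obtained from the regularized solve
`(K + lambda I) alpha = y` on the training kernel matrix — Gaussian-process
regression with point predictions. Labels are centered by their training
mean before the solve and the mean is restored at prediction; this keeps
`alpha` well scaled and changes nothing else.

### Why several cutoffs

A single `r_c` forces a choice: small cutoffs resolve the chemically
dominant first coordination sphere but are blind to packing effects
(ring currents, hydrogen-bond networks reach past 5 Å); large cutoffs see
everything but dilute the short-range signal, so they learn slowly. The
model therefore uses a weighted combination of single-cutoff kernels,

    K = sum_t w_t K_t / sum_t w_t,

with the default ladder r_c = 2, 3, 4, 5, 6, 7 Å and weights
256, 128, 32, 8, 8, 1. The heavy weighting of short cutoffs reflects the
dominance of the first coordination sphere; the long tail of small weights
restores sensitivity to packing. Dividing by the weight sum keeps the
combined kernel unit-diagonal, so `lambda` means the same thing regardless
of how many terms the ladder has. `learning_curve()` reproduces the
expected behavior on synthetic data: the 2 Å kernel plateaus above the
label-noise floor while the combined kernel matches or beats every single
cutoff ("msk" in the output).

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| ς (Gaussian width) | 0.4 Å | smoothing of the neighbor density |
| n_max, l_max | 8, 6 | radial/angular resolution of the expansion |
| zeta | 2 | kernel exponent; sharpens similarity contrast |
| smooth_width | 0.5 Å | cosine taper so descriptors are continuous at r_c |
| lambda | 1e-4 | ridge regularization on the unit-diagonal kernel |
| cutoffs/weights | 2–7 Å / 256…1 | the multi-scale ladder above |

The descriptor hyperparameters are standard values from the SOAP
literature, adequate without system-specific tuning; all are overridable
through `soap_params()` and should in production be selected by
cross-validation on the training set, which is how the multi-scale weights
themselves were originally established. The defaults are recorded in every
model archive, and mismatched parameters refuse to combine at the kernel
level rather than silently producing nonsense.

### Numerical construction

The radial basis is a set of Gaussians centered on `[r_c/n_max, r_c]`,
orthonormalized under the r² measure by the inverse square root of their
overlap matrix (computed on a Gauss–Legendre grid; an eigenvalue floor of
1e-13 relative guards against a numerically dependent basis). Expansion
coefficients use the standard plane-wave-free identity: the angular part of
each neighbor Gaussian is a scaled modified spherical Bessel function
`e^{-x} i_l(x)`, evaluated in its exponentially scaled form so nothing
overflows, with the small-argument series below x = 1e-8 (the self neighbor
sits exactly at x = 0). The power spectrum carries the `sqrt(8 pi^2/(2l+1))`
prefactor that makes its dot product equal the rotationally averaged squared
density overlap; the test suite verifies this identity directly against an
independent SO(3)-quadrature evaluation of the overlap integral on small
environments, at converged basis size (n_max = 16, l_max = 14), to 0.1%
relative.

Atoms exactly at `r_c` are included (closed ball); the cutoff taper sends
their weight to zero, which is also why a neighbor crossing the cutoff
changes the descriptor continuously. Environments are extracted by
enumerating all lattice images within the cutoff (bounded via the
perpendicular plane spacings of the cell), so the neighbor list is correct
even when `r_c` exceeds the cell — the same atom then appears as several
images. The solve uses a Cholesky factorization with an adaptive jitter
(1e-10 escalating tenfold to 1e-6) only when the factorization fails, which
with `zeta = 2` and deduplicated training sets it essentially never does at
`lambda > 0`.

## Training-set curation

Three steps, applied to training data only — held-out and experimental
comparison sets are never curated:

- **Deduplication.** Crystal symmetry makes many environments of one
  structure exactly equivalent; their kernel similarity is 1 up to floating
  point. A greedy scan keeps the first of each group (similarity
  `> 1 - 1e-6` to an already-kept environment *of the same structure*).
  Only within-structure pairs are compared: coincidentally similar
  environments in different crystals are information, not redundancy.
- **Farthest point sampling.** `fps_select()` greedily maximizes the
  minimum kernel distance `d = sqrt(2 - 2k)` to the already-selected set,
  giving near-uniform coverage of environment space; `learning_curve()`
  trains on prefixes of this ordering. The default start is the item with
  the largest total squared distance to all others (the most remote item;
  for centered Euclidean data this is the max-norm point). Structure-level
  FPS uses the mean over environment pairs of the 4 Å kernel as the
  structure similarity, renormalized to unit self-similarity.
- **Outlier pruning.** Reference shieldings can be wrong (bad geometries,
  unconverged reference calculations). `prune_outliers()` computes k-fold
  cross-validation predictions (folds split by structure, never by
  environment, to avoid leakage between symmetry-related environments),
  and flags residuals more than 5 robust standard deviations
  (median/1.4826·MAD) from the median. If the MAD degenerates to zero the
  standard deviation is used, with a warning. On clean synthetic data
  nothing is flagged; with 1% of labels corrupted by 10 standard deviations
  the corrupted labels are recovered at ≥ 90% with ≤ 1% false flags, and
  pruning strictly improves held-out accuracy.

## Referencing and the ranking protocol

Experiments measure shifts δ, models predict shieldings σ; they are related
by `delta = sigma_ref - sigma` with an element-specific reference.
`fit_sigma_ref()` fits the reference with the slope constrained to -1
(`sigma_ref = mean(sigma + delta)`), reporting the unconstrained
two-parameter line only as a diagnostic — the conversion in use is the
constrained one. The conventional 1H and 13C references for GIPAW-quality
shieldings are 30.8 and 169.5 ppm.

For ranking, per-atom predicted shifts are averaged over groups of
equivalent nuclei (unweighted mean — the fast-exchange convention, e.g.
methyl rotation), compared with the assigned experimental resonances by
unweighted RMSE over labels, and candidates are sorted; a candidate is
*accepted* when its RMSE is within the confidence threshold, default
0.49 ppm. That number is calibrated for GIPAW-quality 1H shifts and is a
configurable default, not a law; for other nuclei or reference methods it
must be re-benchmarked.

## What the synthetic data does and does not emulate

`generate_crystal()` packs atoms uniformly into a cubic cell under a
minimum periodic distance constraint (default 16 atoms, 6 Å cell, 1 Å
minimum — about the atom density of a real organic crystal), with an
H-rich composition (H:C:N:O = 0.5:0.3:0.1:0.1). `oracle_rule()` labels
each atom with

    sigma = a_s - b * N(r_s) + c * sum_{r <= r_max} exp(-r / r_0) + noise

(defaults: baselines 30/170/250/280 ppm for H/C/N/O, b = 2 ppm per neighbor
within r_s = 1.6 Å, tail c = 1 ppm with decay 3 Å capped at r_max = 7 Å,
noise 0.1 ppm). The short-range term dominates and the tail spans exactly
the cutoff ladder, so single-cutoff and combined kernels are discriminable —
the property the learning-curve tests rely on. `make_polymorph_family()`
produces decoy "polymorphs" by Gaussian coordinate perturbation
(0.2 Å per coordinate in the ranking tests: decoys must differ by more than
the 0.3 ppm observation noise for a confidence-interval protocol to be able
to discriminate at all, just as real CSP decoys are distinct packings, not
thermal jitter of the true one).

What this emulates well: periodic geometry, symmetry-equivalent
environments (via supercells), label noise, short- vs long-range structure,
and candidate families containing the truth. What it does not: chemistry.
There are no bonds, no hydrogen-bond geometry, no real polymorph
energetics, and the oracle is a two-term radial rule rather than quantum
mechanics. Passing tests therefore demonstrate that the machinery is
correct and behaves as designed, not that the default hyperparameters reach
any particular accuracy on real crystals — that requires DFT-labeled
training data.

## Problem sizes and design choices in the tests

The study-scale checks use three independently seeded worlds of 78
sixteen-atom crystals (~620 1H environments each), a fixed ~100-environment
held-out split, and learning-curve sizes 60–500 — large enough for the
multi-scale ordering to be stable across seeds, small enough to run
comfortably on one CPU. The SO(3)-quadrature kernel oracle runs on 2–3-atom
toy environments where the rotation integral converges with 24×18×24
Euler-angle nodes. Where the design was genuinely open we chose: JSON as the
single-file model archive (self-describing, versioned, byte-reproducible —
identical seeds give identical archives); per-element models rather than a
joint multi-element regressor; regression on shieldings with referencing
applied downstream; and train/test splitting always by structure.

## Known limitations

- No predictive variance: `sigma(X)` is a point prediction; the acceptance
  decision rests entirely on the externally calibrated RMSE threshold.
- Dense kernels: training cost is cubic in the retained environment count;
  no sparse/low-rank approximation is provided.
- Elements are fixed to H/C/N/O; extended-XYZ is the only structure format
  (convert CIF externally).
- The outlier rule (robust z on CV residuals) is a transparent stand-in for
  more elaborate curation statistics; its thresholds are defaults, not
  dogma.

## A worked session

```{r, eval = FALSE}
library(soapshift)

crystals <- lapply(1:40, function(k)
  generate_crystal(16, seed = 100 + k, id = paste0("c", k)))
labels <- oracle_table(crystals, oracle_rule(), seed = 1)

model <- shift_model(crystals[1:30], labels, element = "H", seed = 1)
summary(model)

test <- shift_dataset(crystals[31:40], labels, "H")
evaluate_shifts(predict(model, test)$sigma_ppm, test$y)

lc <- learning_curve(shift_dataset(crystals, labels, "H"),
                     sizes = c(50, 100, 200), seed = 1)
plot(lc)
```
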