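---
title: "Predicting protein stability changes from voxelized structure representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein stability changes from voxelized structure representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabscan)
```

## The model

stabscan predicts the change in folding free energy
($\Delta\Delta G$, kcal/mol; positive = destabilizing) caused by a single
amino-acid substitution, using a two-stage architecture.

**Stage 1 — self-supervised representation.** For every residue, the local
atomic environment is the set of atoms within 9 Å of its C$\alpha$,
*excluding all atoms of the residue itself* (masking). The environment is
expressed in a backbone-local coordinate frame, binned into a cubic grid of
1 Å voxels with six occupancy channels (C, N, O, H, S, P), smoothed with a
Gaussian, and fed to a 3D convolutional network (three conv blocks with 16,
32 and 64 filters of edge 3, each conv $\to$ batchnorm $\to$ leaky ReLU
$\to$ 2³ max-pool; then fully-connected layers of 100 and 20 nodes). The
network is trained to classify the masked wild-type amino acid by
cross-entropy. The 100-node layer, post-activation, is the *residue
representation*.

**Stage 2 — supervised regression.** For a variant (wild type $w$, mutant
$m$) the feature vector concatenates the 100-d representation, one-hot
encodings of $w$ and $m$ (20 + 20), and the background frequencies of $w$
and $m$ in the training structure set (2), for 142 dimensions. Targets are
compressed with the Fermi (switching) function
$$F(\Delta\Delta G) = \frac{1}{1 + e^{-\beta(\Delta\Delta G - \alpha)}},
\qquad \beta = 0.4\ \mathrm{(kcal/mol)^{-1}},\ \alpha = 3.0\ \mathrm{kcal/mol},$$
which focuses training on the roughly $[-1, 7]$ kcal/mol range where
physics-based reference calculations are most reliable and where
disease-relevant destabilization lives. A fully-connected network
(128/64/16 nodes, batchnorm + leaky ReLU between layers, scalar output
through a sigmoid) is fit by mean absolute error *in Fermi space*
(MAE$_F$). Ten such models are trained with different seeds; the prediction
is the ensemble median in Fermi space, mapped back to kcal/mol by the
inverse transform. kcal/mol MAE is a secondary metric obtained after
inversion.

Reference targets of this kind are usually produced by a physics-based
cartesian $\Delta\Delta G$ protocol whose raw scores must be divided by 2.9
to land on a kcal/mol-like scale (`convertRosettaUnits()`); this package
does not run such a protocol, it consumes its outputs (or synthetic
stand-ins, below).

## Assumptions and input contract

* Inputs are single protein chains in PDB format, already protonated and
  repaired by external tools. `readStructure()` *validates* rather than
  fixes: it warns when fewer than 5% of atoms are hydrogens (a proxy for an
  un-protonated file), drops waters/hetero-atoms and alternate locations
  other than A, uses model 1 of multi-model files, and skips residues
  without a canonical amino-acid mapping. Author residue numbering is never
  re-indexed, so outputs join against variant tables keyed by reference
  numbering.
* Elements outside the six channels (metals, selenium) have no stated
  handling in the reference setup; they are kept in the atom table but
  dropped from featurization, with a warning at parse time.
* Predictions are one-sided: the model is trained on forward substitutions
  in wild-type structures and does not satisfy the
  $\Delta\Delta G(w \to m) = -\Delta\Delta G(m \to w)$ anti-symmetry
  condition. No correction is attempted.
* Variants at disulfide-bonded cystines (sulfur pairs closer than 2.5 Å)
  are excluded from training data, because reference pipelines do not model
  them; at prediction time wild-type cysteines are *flagged*
  (`wt_is_cysteine`), never dropped, and such predictions should be treated
  as unreliable.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| sphere radius | 9 | Å | environment definition |
| voxel edge | 1 | Å | grid resolution; side = 18 voxels |
| blur sigma | 1.0 | Å | one voxel edge; smooths discretization |
| conv filters | 16, 32, 64 | – | representation capacity |
| repr learning rate / batch | 3e-4 / 100 | – / residues | Adam |
| Fermi $\beta$, $\alpha$ | 0.4, 3.0 | 1/(kcal/mol), kcal/mol | target transform |
| downstream layers | 128, 64, 16 | nodes | regressor capacity |
| downstream lr / batch | 5e-4 / 40 | – / variants | Adam |
| ensemble seeds | 0..9 | – | median of 10 members |
| SASA probe | 1.4 | Å | water-sized rolling probe |
| burial cutoff | 0.2 | relative SASA | exposed iff $\geq$ 0.2 |
| inverse-Fermi clamp | 1e-4 | – | invertibility bound |

## Design choices where the design was open

Several details are not pinned down by the published description of this
family of models; the package makes them explicit, fixed choices:

* **Grid layout.** The sphere radius and voxel volume determine only the
  resolution; we use the minimal cube circumscribing the 9 Å sphere
  (18³ voxels, centers at half-integer coordinates).
* **Local frame.** No orientation convention is stated. We build a
  Gram–Schmidt frame from the backbone: origin at C$\alpha$, first axis
  along N−C$\alpha$, second the orthogonal component of C−C$\alpha$, third
  their cross product. Because atom coordinates are expressed in this frame
  before binning, every residue's grid is exactly invariant under rigid
  motion of the input structure — a property the test suite asserts to
  1e-6 after blurring.
* **Binning rule.** Nearest-voxel-center binning (not trilinear
  splatting), with Gaussian blurring as the separate smoothing step. This
  makes the voxelization contract unambiguous enough to check against an
  independent brute-force oracle, exactly.
* **Blur width.** The blurring step is stated without a width; we default
  to $\sigma$ = 1 Å (one voxel edge), kernel truncated at $2\sigma$ and
  normalized to unit sum, so per-channel mass is conserved except where it
  falls off the cube boundary.
* **Block order** conv → batchnorm → leaky ReLU (slope 0.01) → max-pool
  (edge 2, stride 2), "same" convolution padding: 18³ → 9³ → 4³ → 2³, so
  the flattened convolutional output has 512 features.
* **Early stopping.** Only a learning curve is published, no stopping
  rule; we stop on validation accuracy (representation) or validation
  MAE$_F$ (downstream) with patience 10 and 25 epochs respectively, and
  return the best-validation checkpoint.
* **Batchnorm priming.** Running statistics are initialized from the first
  training batch (a momentum-1 priming pass) instead of the conventional
  (0, 1) init. With the small number of batches per epoch used at desk
  scale, EMA warm-up from (0, 1) takes ~100 updates during which eval-mode
  metrics are meaningless; priming makes validation-based early stopping
  honest from epoch 1 without changing what the network computes.
* **Inverse-transform clamp.** The Fermi function is not invertible at 0
  or 1, so scores are clamped to $[10^{-4}, 1 - 10^{-4}]$ (saturating
  predictions at roughly $[-20, +26]$ kcal/mol), with clamping events
  warned about.
* **Median space.** The ensemble median is taken in Fermi space; since the
  inverse transform is strictly monotone, the median commutes with it, so
  this choice is observationally equivalent to a kcal/mol-space median.
* **Boundary conventions.** Relative SASA exactly 0.2 classifies as
  *exposed* ($\geq$ convention); an allele frequency exactly at a bin
  threshold goes to the *lower* (rarer) bin. Both boundaries are stated
  cutoffs whose side is otherwise unspecified.
* **Self-substitutions** are emitted in scan tables with
  $\Delta\Delta G = 0$ and a flag, so every site contributes a complete
  20-row block and downstream joins can rely on a full matrix.
* **SASA.** Shrake–Rupley with a 1.4 Å probe on heavy atoms, normalized by
  Sander–Rost per-residue maxima. Terminal or unusually exposed residues
  can slightly exceed relative SASA 1; values are deliberately not
  clipped.

## What the synthetic generators emulate — and what they do not

Training the real model requires a large homology-reduced structure set
and saturation-mutagenesis reference calculations for dozens of proteins;
neither is desk-scale. The package therefore ships seeded generators that
preserve the *structure* of the problem:

* `makeToyStructure()` builds backbones from ideal internal coordinates
  (helix $\varphi = -57^\circ$, $\psi = -47^\circ$; extended
  $\varphi = \psi = 180^\circ$; compact bundles of ≥ 3 packed antiparallel
  helices whose interiors fall below the 0.2 burial cutoff). Each residue
  carries one pseudo side-chain atom at the C$\beta$ position whose element
  class depends on residue type (S: Cys/Met; O: Ser/Thr/Asp/Glu/Asn/Gln/Tyr;
  N: Lys/Arg/His/Trp; C: others). Random sequences are generated in runs of
  a single residue type (geometric lengths, mean ≈ 4), so the masked
  residue's identity correlates with its neighbours' side-chain elements —
  this is what gives the representation model signal to learn at toy
  scale. Fixture hydrogens are the backbone amide H only, which keeps the
  hydrogen fraction above the un-protonated warning threshold.
* `makeSyntheticDdg()` draws targets from a fixed deterministic rule,
  $\Delta\Delta G = s(w)\, d(w, m)\,(1 + b \cdot \mathrm{buried}) -
  0.3 + \varepsilon$, with $s$ built from residue volumes, $d$ from
  Kyte–Doolittle hydropathy and volume differences (plus a constant), $b =
  0.8$, and $\varepsilon \sim N(0, 0.2\ \mathrm{kcal/mol})$. The constants
  were calibrated once so that ≥ 90% of generated values fall in
  $[-1, 7]$ kcal/mol, mirroring the range the Fermi transform focuses on.
* `makeVariantTable()` emulates a clinical/population variant table:
  pathogenic labels with probability increasing in the true
  $\Delta\Delta G$, log-uniform allele frequencies in $[10^{-6}, 10^{-1}]$,
  and a stated rate of wild-type-mismatched decoy rows to exercise join
  rejection.

Passing the recovery tests on these fixtures demonstrates that the
pipeline is wired correctly end to end — featurization is informative,
training optimizes what it claims to, the ensemble median and inverse
transform compose properly. It does **not** demonstrate accuracy on real
proteins: the fixtures have no rotamers, no physics, no experimental
noise structure, and a deliberately learnable target rule.

## Problem sizes used by the test suite

The suite trains reduced models so that everything runs on one CPU: the
representation learnability check uses ~1,000 environments from 24 toy
helices with 6/12/24 filters and a dozen epochs (held-out-protein
accuracy is required to beat 3× the 1/20 chance rate); the downstream
recovery check trains the representation model on its own set of 8
compact bundles and the regressor on 16 further bundles of 42 residues
(13 training, 1 validation, 2 held out; ~12,700 variants) with a 3-seed
ensemble, and is required to recover held-out-protein Pearson ≥ 0.9 and
MAE ≤ 0.3 kcal/mol against the noiseless generative rule. The
published-scale configuration (16/32/64 filters, 10 seeds, 100-epoch
budgets) is the package default.

One further split matters: the structure set used to train the
representation model is kept *disjoint* from the proteins whose
$\Delta\Delta G$ values train and test the regressor, exactly as the
two-stage setup separates the self-supervised structure corpus from the
supervised scan targets. At desk scale this is not just fidelity: when
stage 1 is trained on the regressor's own proteins, its embeddings carry
protein-specific structure that the regressor memorizes, and
held-out-protein recovery measurably degrades.

## Known limitations

* No anti-symmetry: reverse-variant predictions are unreliable by
  construction.
* Cysteine predictions at disulfide positions are flagged, not fixed.
* Single chains only: no interface $\Delta\Delta G$, no nucleic acids, no
  mmCIF parsing, no protonation.
* The in-package networks are plain R + a small C++ convolution kernel;
  they are deliberately desk-scale and make no attempt at GPU-scale
  training of the published configuration.
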