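---
title: "Methods: simulating, projecting and classifying atrial fibrillation drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, projecting and classifying atrial fibrillation drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`afdriverloc` treats non-invasive localization of atrial fibrillation (AF)
drivers as a supervised image-classification problem.  A driver — a
re-entrant rotor sustaining the arrhythmia — sits in one of seven
clinically used atrial regions (posterior left atrial wall, the four
pulmonary veins, right atrial appendage, right atrial free wall); an
eighth class, label 0, means "no driver".  The pipeline is fully
synthetic and self-contained:

1. **Tissue simulation.** AF propagation on a closed triangulated atrial
   surface, with a three-variable phenomenological ionic model and
   anisotropic monodomain coupling.
2. **Forward projection.** Transmembrane potentials map linearly to
   body-surface potentials (BSP) through an area-weighted current-dipole
   sum in an infinite homogeneous medium, assembled once as a transfer
   matrix and referenced to the Wilson Central Terminal (WCT).
3. **Signal conditioning.** Calibrated additive white Gaussian noise
   followed by a fourth-order zero-phase Butterworth band-pass (3–30 Hz),
   then selection of a 64-electrode vest.
4. **Tensorization.** Each 64-electrode frame becomes an image in one of
   two layouts (a 3-channel front/sides/back stack, or a 1-channel
   unrolled cylinder with mirror columns), resized bilinearly.
5. **Classification.** A compact convolutional network (32/64/64 filters,
   dense 128/64, dropout 0.6, softmax over 8 classes) trained with
   class-weighted cross-entropy, early stopping, learning-rate reduction
   and checkpointing.
6. **Evaluation.** Accuracy, Cohen's kappa, per-class sensitivity and
   specificity, and an SNR robustness sweep (5–50 dB, repeated noise
   draws).

## The tissue model and its assumptions

Each node obeys
$\partial V_k/\partial t = -I_{ion}/C_m - \sum_i D_{k,i}(V_k - V_i)/d_{k,i}^2$,
with per-edge diffusion $D_{k,i} = D_{long}\cos^2\alpha +
D_{trans}\sin^2\alpha$, where $\alpha$ is the angle between the local
fiber direction and the edge.  Fibrotic nodes have all incident diffusion
set to zero.  The system is integrated with fixed-step RK4 (default
`dt = 0.05` ms) after an explicit stability pre-check
(`dt <= 2.6 / (2 max_k sum_i D_{k,i}/d_{k,i}^2)`), and the transmembrane
potential is recorded at 500 Hz.

The ionic model (`atrial3v`) is a three-variable phenomenological model
(fast inward, slow outward, slow inward currents gated by two recovery
variables) rather than a biophysical human-atrial current set.  Its
defaults were chosen once, before any classifier was trained, to give an
atrial-like single-cell action potential (APD90 ≈ 128 ms) and stable
re-entry at the package's mesh resolutions; they are not tuned to any
downstream metric.  The transmembrane potential is kept in normalized
units (0 rest, ≈1.3 peak); the forward model is linear, and tensors are
normalized per-frame downstream, so absolute scale is immaterial.

**Diffusion defaults.** No published values exist for the discrete
graph-diffusion coefficients at these resolutions.  Discrete propagation
imposes a lower bound on the per-edge coupling $D/h^2$ below which wave
fronts block, so the defaults scale with the squared mean edge length:
$D_{long} = 0.042\,h^2$, $D_{trans} = D_{long}/2$.  On the default
2,048-node mesh this gives a longitudinal planar conduction velocity of
roughly 0.6 mm/ms.  A transverse-to-longitudinal velocity ratio of 1/2
(diffusion ratio 1/4) was the target, but on coarse meshes it would push
transverse coupling below the block threshold; the ratio 1/2 in diffusion
(≈0.7 in velocity) is the compromise, recorded here rather than hidden.

**Rotor induction.** Re-entry is seeded by a phase-distribution initial
condition: single-cell states along one action-potential cycle are laid
out as a phase pinwheel around the target region's center, whose free
wavefront end immediately curls into a rotor.  An explicit S1–S2
cross-field protocol is also implemented (`rotor_method = "s1s2"`), but
two-pulse timing is fragile on coarse synthetic geometry, so the seeded
pinwheel is the default; it is the standard numerical equivalent of
cross-field induction.  An archimedean twist in the seed was tried and
rejected: it packs the spiral arms tighter than one wavelength and
extinguishes the wave on coarse meshes.  On a closed surface the index
theorem forces a mirror-image singularity near the antipode of the seeded
core; the labeled driver is the seeded one, and the phase-singularity
cross-check (below) confirms the labels.

**Ground-truth labels.** Frames of a rotor episode carry the target
region id while the tissue remains active (rotors may self-terminate, and
those tail frames honestly revert to label 0); planar-wave, focal-pacing
and quiescent episodes are labeled 0 throughout.  Labels come from the
protocol, not from a detector; an independent Hilbert-phase detector
(winding number ±1 of the instantaneous phase around each node's ordered
1-ring) is used as a cross-check and must agree on ≥90% of driver frames
in the test suite.  Focal pacing is deliberately labeled 0: the label
scheme tracks re-entrant drivers, and focal episodes double as
structured driver-free data.

## Forward model

Gradients of the nodal potential field are obtained per node by a
least-squares quadratic fit over at least nine stencil neighbors
(1-ring, expanded ring-by-ring as needed); rank-deficient stencils fall
back to a linear fit and are flagged.  Each node contributes
$w_k\,(\vec r_k/r_k^3)\cdot\nabla V_{m,k}$ at an observation point, with
$w_k$ the barycentric third of incident triangle areas.  Composing the
(sparse) gradient operator with the dipole kernel at every electrode
yields the transfer matrix; a boundary-element torso is a declared
extension point, not implemented, because no imaged torso geometry exists
in this synthetic world.  Amplitudes are in arbitrary consistent units —
physical conductivity constants cancel under per-tensor normalization.

The WCT correction subtracts from every electrode row the average of the
three WCT rows (the electrodes nearest the two shoulders and the
lower-left torso), so referenced potentials average to zero over the WCT
leads for any input, to machine precision.  The matrix form of the
correction follows the referencing equation (output minus WCT-average)
rather than the sparser matrix definition sometimes written for it, which
would alter only the WCT rows and break that invariant.

## Signal conditioning

Noise is calibrated per electrode against the clean signal's mean power,
is added *before* filtering, and each (SNR, repetition) pair derives its
own sub-seed.  The band-pass is a Butterworth design (analog prototype,
band transformation, bilinear transform with pre-warping) applied
forward-backward, so filtering is zero-phase and frame labels stay
aligned; the single-pass response is −3 dB at 3 and 30 Hz by
construction.  Filtering all channels before vest subselection is
equivalent to the reverse order for a linear filter.

## Tensor layouts

The canonical 64-channel order is front panel row-major, back panel
row-major, then the 16 side electrodes column-major (left pair, right
pair, rows 3–6).  The 3-channel layout stacks front / sides / back as a
6×4×3 array; the eight unoccupied side cells are zero.  The 1-channel
layout unrolls the vest cylinder into 12 columns
(front 4, left side 2, back 4, right side 2), fills the eight empty side
cells with the mean of the three nearest occupied electrodes under
wrap-aware Chebyshev grid distance (ties broken by row, then column), and
adds two mirror columns per side (16 columns total) so the seam of the
cylinder is visible to the convolution.  The exact side-column order and
gap convention are not uniquely determined by the published figure; the
package's choice is recorded in `default_vest_layout()` and is
config-switchable.  Bilinear resizing uses the align-corners convention,
chosen for exact corner reproduction.

## Classifier and training controls

Convolutions use 'same' zero padding (consistent with the architecture's
stated minimum input of 8×8 surviving three 2× poolings); pooling is 2×2
stride 2 with floor semantics.  Dropout (rate 0.6) sits after each dense
ReLU layer and is inference-silent.  The loss is categorical
cross-entropy with inverse-frequency class weights
`w_c = Total / (K_present * n_c)` (mean weight 1 over samples).
Training controls not stated numerically anywhere are package defaults,
declared here: Adam at learning rate 1e-3, batch 32, early-stop patience
50, learning-rate factor 0.5 with patience 20, monitored on the training
loss, maximum 1,000 epochs; the checkpointed best model is returned.  The
whole training path (initialization, shuffling, dropout) is driven by a
single seed and is bit-reproducible.

The reduced smoke/test configuration (39×96×1 input, frame stride 6,
15 epochs) exists to keep desk-scale runtimes near 10 minutes on one
CPU; the topology is identical to the headline shapes.

## What the synthetic world does and does not establish

The generator emulates: multiple AF episodes of 2–5 s at 500 Hz; drivers
across all seven regions plus driver-free segments; 64-electrode vests;
SNR 5–50 dB; random fibrosis.  It does not emulate imaged anatomy
(realistic atrial or torso geometry, wall thickness), biophysical ionic
currents, inter-patient variability, or measurement artifacts other than
white noise.  A green end-to-end test therefore establishes that the
pipeline's mechanics are sound — labels are learnable from projected,
corrupted, filtered BSP images at the stated SNR — not that the reported
clinical-scale accuracies transfer to real recordings.  Published
headline accuracies from multi-torso, CT-derived corpora are
deliberately *not* acceptance targets; the acceptance suite instead
checks synthetic-recovery performance, the split-scheme ordering
(time-independent above consecutive-blocks, the overfitting signature),
noise monotonicity of the sweep, and exact analytic invariants.

## Numerical choices and degenerate inputs

* Stability: integration refuses `dt` above the RK4 diffusion bound and
  suggests a safe value; non-finite potentials abort with the frame index.
* Gradient stencils: rank-deficient quadratic fits fall back to linear,
  flagged in diagnostics; fully degenerate stencils error.
* Dipole kernel: observation points inside a guard radius (1% of torso
  radius) are rejected, naming the electrode.
* Undefined rates (empty class TPR/TNR, kappa with `p_e = 1`) are
  signaled explicitly — NA with a warning, or an error — never silently 0.
* Zero-variance tensors normalize to zeros and carry a `degenerate` flag.
* All randomness flows from one run seed via `derive_seed(seed, stage)`.

## Known limitations

Anisotropy is mild at coarse resolutions (see diffusion defaults); rotors
on the 2,048-node mesh occasionally self-terminate in some regions
(honestly relabeled); the torso is an elliptic cylinder, so electrode
geometry is only vest-like; the phase-singularity detector is a
cross-check, not an independent labeling pathway; and transfer-learning
backbones are out of scope (the 1→3 channel replication utility exists
for them).
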