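---
title: "Learned post-processing of cryo-EM density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned post-processing of cryo-EM density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emrestore)
```

## The problem

Single-particle cryo-EM reconstructions lose contrast at high spatial
frequency: the Fourier amplitudes of a raw map are attenuated roughly as
$\exp(-B s^2/4)$, where $s$ is spatial frequency in 1/Å and $B$ (in Å²)
measures the global contrast loss. Classical sharpening inverts this decay
with a single global $B$, which over-sharpens the good parts of a map and
under-sharpens the bad parts whenever local quality is heterogeneous —
which it almost always is. Local methods address this but need extra
inputs: a mask, a local-resolution map, or a fitted atomic model.

`emrestore` implements the alternative: a 3D U-net trained on pairs of
(raw experimental-style map, tightly masked locally sharpened target) that
learns masking-like and local-sharpening-like operations in a single
pass, requiring nothing but the map (or its two half maps) at run time.
The package contains the whole surrounding apparatus — MRC I/O,
resampling, noise normalization, cube chunking with overlap-averaged
reassembly, the network and its training loop, a synthetic data generator,
and an FSC-based evaluation suite — so the entire method is exercisable
end to end on synthetic volumes on one CPU.

## The processing model

A map is prepared for the network in three canonical steps:

1. **Resampling to 1 Å/voxel.** Molecular building blocks have fixed
   physical size, so a fixed working grid lets the network learn
   scale-consistent features. We resample by Fourier zero-padding/cropping:
   it is exactly band-limited, linear and deterministic, and the inverse
   (`resize_to_original()`) restores the original grid at the end. A
   real-space cubic-spline path exists behind `method = "spline"` for
   maps with content near Nyquist where ringing is a concern.
2. **Noise-statistics normalization.** The map is affinely rescaled so
   the noise region has mean 0 and standard deviation 0.1. The noise
   region defaults to the corner/edge shell of the box (outside the
   centered sphere of radius $0.9\,\min(N)/2$, intersected with the outer
   15 % shell), with a 4-MAD trim against stray signal; an explicit mask
   overrides. Both the region rule and the trim are package choices — the
   convention itself (noise at (0, 0.1)) is the classical one.
3. **Chunking.** The network consumes cubes (64³ by default). Inference
   uses overlapping cubes at stride 16 and averages the overlaps on
   reassembly; per axis the origins are `0, stride, 2·stride, …` with the
   final origin clamped to `N − cube`, which guarantees full coverage
   with at most one irregular step per axis.

The network itself (`unet_config()`, `build_model()`) is a 3-level 3D
U-net: three same-padded 3×3×3 convolutions per block with group
normalization (8 groups) and per-channel PReLU, 32/64/128 filters,
stride-2 strided convolutions down, kernel-2 stride-2 transposed
convolutions up, concatenation skips, and a final linear 1×1×1
convolution. Where the published architecture's fine detail was not
available (kernel sizes, group counts, skip wiring, output activation),
the values above are this package's own choices, stated here rather than
attributed. The final layer is initialized small, so an untrained
model's output RMS sits near the 0.1 working noise scale — with tightly
masked (mostly zero) regression targets this keeps the early
mean-absolute-error descent well-scaled instead of spending it on a
gross rescaling.

The forward and backward passes are implemented from scratch in C++
(channels-last feature maps with a one-voxel zero ring, so a same-padded
convolution is 27 BLAS `sgemm` calls on row-shifted views). The backward
pass is validated in the test suite against central finite differences on
a kink-free configuration (linear PReLU, squared loss), where it agrees
to ~1e-4 relative.

Training follows the reference recipe: batches of 8 cubes, SGD with
initial learning rate $10^{-3}$ halved when the validation loss has not
improved (by at least $10^{-5}$ relative — our concretization) for 5
consecutive epochs, MAE loss, and augmentation by random 90° rotations
(applied to input and target), Gaussian blur of the input only
(σ ~ U(0.3, 1.5) voxels), and patch corruption of the input only (16³
sub-box replaced by N(0, 0.1) noise), each with probability 0.3. Blur and
corruption never touch the target: it is the clean supervision signal.
Augmentation strengths are package choices.

## The synthetic data generator

Real training data for this method are EMDB half-map pairs and locally
sharpened, tightly masked targets. The generator emulates their
statistical structure without any external data:

* a **pseudo-molecule**: a self-avoiding random walk with 3.8 Å steps
  (backbone-like spacing), rendered as a sum of Gaussians with per-atom
  width $\sigma^2 = B_{atom}/(8\pi^2) + 0.8^2$ Å² — the "sharp"
  reference;
* **contrast degradation**: Fourier amplitude attenuation
  $\exp(-B s^2/4)$ (the crystallographic amplitude convention — B
  conventions differ by factors of 4, so this is stated explicitly), or a
  smooth position-wise blend of two attenuation levels to emulate
  heterogeneous local quality;
* **half maps**: two independent noise draws added to the degraded
  signal; the full map is exactly their average;
* a **tight mask**: the sharp map thresholded at 5 % of its maximum and
  dilated by a 2-voxel ball; the **target** is the sharp map under that
  mask, rescaled so its 95th in-mask percentile is 1 (masked maps have no
  noise region, so noise normalization does not apply to them).

Default study conditions: 96³ boxes at 1 Å/voxel, 60–200 atoms, global
$B \in [50, 200]$ Å², white noise with peak signal-to-noise drawn in
[2, 6]. The generator reproduces what the method assumes — band-limited
signal, B-factor contrast loss, independent half-map noise, tight
targets. It does not model CTF effects, colored solvent noise beyond an
optional band-limited option, lipid/detergent belts, or reconstruction
artifacts; passing tests on it demonstrate that the pipeline's machinery
and learning dynamics work, not that the trained weights transfer to
experimental maps.

Two physics oracles pin the simulator down: the Guinier slope of
$\log(P_{degraded}/P_{sharp})$ against $s^2$ recovers $-B/2$, and
half-map FSC resolution degrades monotonically with the noise level.

## Evaluation

`fsc()` bins Fourier voxels into shells one Fourier voxel wide (rounded
integer radius; per-axis normalized frequency for anisotropic boxes) and
computes the standard normalized cross-correlation per shell.
`resolution_at_threshold()` takes the *first* crossing, linearly
interpolated, excluding DC — curves that never fall below threshold
return the Nyquist resolution flagged `"nyquist"`, curves that never
reach it return `Inf` flagged `"below"`, and curves that start below the
threshold but re-cross (typically one noisy near-DC shell) are measured
at the first down-crossing and flagged `"crossed-recrossing"`. The threshold is 0.5
against an external reference and 0.143 between half maps. `masked_fsc()`
softens the mask edge with a cosine ramp (default 3 voxels, exact
Euclidean distance transform) to limit mask-correlation artifacts.

## The desk-scale training protocol

The package's acceptance experiment trains a reduced U-net (filters
8/16/32) on 30 synthetic maps and evaluates on 10 held-out maps, under
the pinned recipe (batch 8, SGD lr $10^{-3}$, plateau ×0.5/patience 5,
MAE, ≤ 25 epochs). Within one CPU-scale run three scheduling choices make
the optimization land:

* **Training patches.** The network is fully convolutional, so training
  does not require the 64³ inference cube. The protocol trains on 24³
  crops drawn from the stride-32 cube extraction, three quarters of them
  rejection-sampled to contain at least 8 % target support (supervision
  on a tightly masked target is otherwise extremely sparse) and one
  quarter unbiased so noise-dominated regions stay in-distribution —
  group normalization makes the network's response depend on cube
  content, so regions seen only at inference would otherwise be
  out-of-distribution. For the same reason inference in this experiment
  uses the same cube size as training, with a half-cube stride: overlap
  averaging suppresses the decorrelated part of the per-cube error. The
  64³/stride-16 contract remains the package default for full-scale use.
* **Momentum.** The reference recipe says only "stochastic gradient
  descent"; the package default is plain SGD. At a few hundred steps the
  MAE gradient (per-voxel magnitude $1/(BV)$, sparse support) cannot
  move the parameters far enough, so the protocol uses the momentum
  variant (0.995) of the same optimizer.
* **Augmentation** is reduced to rotations only; blur and corruption
  make the task strictly harder and pay off only at data scales where
  overfitting, not optimization, is the binding constraint.

Problem sizes throughout the suite (map counts, box sizes, epochs) are
chosen so the full test suite and the acceptance script run in minutes on
a single CPU; the protocol above is the package's standing definition of
its desk-scale experiment.

## Numerical choices and degenerate inputs

* Resampled output shapes round half away from zero; inversion uses the
  recorded original shape, never re-derivation.
* Even-size Fourier resizing splits (pad) or folds (crop) the Nyquist
  bin so real input stays real and crop is the exact adjoint of pad.
* Flat maps are rejected by `estimate_noise_stats()` (no noise scale);
  all-zero maps are rejected by `fsc()` (undefined normalization) and
  `make_mask()` (empty support).
* Maps smaller than the cube are corner-placed and padded with the noise
  mean (≈ 0 after normalization); padding is cropped on reassembly.
* Gradient clipping (global norm, default 1.0) guards the training loop;
  the plateau counter resets both on improvement and after each decay.
* Anisotropic voxel sizes are rejected at 1 % spread unless explicitly
  allowed, in which case each axis is resampled independently.

## Known limitations

* The synthetic generator's realism gap (no CTF, simplified noise)
  means desk-scale results quantify machinery, not transferable weights.
* Kernel-2 transposed convolutions avoid checkerboard artifacts but halve
  the upsampling receptive field relative to kernel-3 alternatives.
* The hand-written engine is single-threaded by design (deterministic,
  BLAS-bound); large-map inference at stride 16 is minutes-scale on CPU.
* Group normalization ties the network's response to cube content;
  matching train and inference cube distributions matters (see above).
* At desk scale the trained model's gains are masking/denoising-like:
  the acceptance experiment shows large improvements in validation MAE
  and in real-space correlation against the targets, while the unmasked
  FSC@0.5 resolution of predictions does not yet beat the raw input's
  SNR-limited agreement — reconstructing detail beyond that band needs
  orders of magnitude more optimization than a CPU-scale run affords.
  The corresponding acceptance assertion is kept strict and documents
  this as a failing expectation rather than a weakened one.
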