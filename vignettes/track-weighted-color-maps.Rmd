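---
title: "Track-weighted color maps: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-weighted color maps: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectre)
```

## The method in one paragraph

Deep-brain-stimulation targets such as the subthalamic nucleus are too
small and too uniform on conventional MRI contrasts to reveal their
internal functional organization, yet that organization is mirrored in
their long-range connectivity. The idea implemented here is to encode
*where a pathway goes* as a smooth color: a template-space color
gradient assigns, say, green to frontopolar cortex, blue to
sensorimotor regions and red to occipito-parietal regions; the gradient
is warped into each subject's native space; then, for every voxel `r`
of a small target region, `N` streamlines are propagated through the
diffusion-tensor field and the warped color field `c_k` is summed along
them:

$$C_k(r) \;=\; \sum_{f=0}^{N-1} \sum_{n=1}^{L_f} c_k\!\left(x_n^{r,f}\right),$$

with the color evaluated at the fractional streamline positions
`x_n^{r,f}` by trilinear interpolation. The resulting K-channel map
paints each target voxel with the blended color of the remote regions
its streamlines reach, so the connectivity *pattern* becomes directly
visible as a color gradient across the nucleus.

Two deliberate properties of the sum deserve emphasis:

* **No length normalization.** Longer streamlines contribute more.
  This is the track-weighting principle: a voxel strongly connected to
  a distant colored territory accumulates proportionally more of that
  territory's color. On a constant unit color field the map value is
  exactly the total number of streamline points, which the test suite
  uses as an oracle.
* **Linearity in the color field.** Aggregating `c + c'` equals the
  sum of the separate aggregates; this makes the maps interpretable as
  superpositions of per-territory contributions and is asserted
  exactly in the tests.

## The template color gradient

The shipped fronto-occipital scheme is a sum of three isotropic
Gaussians, each feeding one RGB channel:

$$c(r) \;=\; \sum_{i=1}^{3} a_i \exp\!\left(-\frac{|r_i - r|^2}{2\sigma^2}\right)$$

with `a1 = (0.5, 0, 0)` at `r1 = (0, -60, 70)` mm, `a2 = (0, 1, 0)` at
`r2 = (0, 70, 0)` mm, `a3 = (0, 0, 1)` at `r3 = (0, 20, 70)` mm and a
shared width of `sigma = 50` mm (MNI coordinates). Because each
Gaussian carries exactly one channel, every channel depends only on
the distance to its own center — a separation the tests verify against
a scalar oracle. The field is rasterized onto a template grid
(`rasterize_gradient()`), optionally restricted to a tissue or lobe
mask (`restrict_to_mask()`, e.g. gray-matter-only accumulation, or
prefrontal-only coloring for internal-capsule work), and warped to
subject space by a dense deformation field.

The template rasterization resolution is not dictated by the method;
1 mm isotropic is the package default and is configurable. Values
rasterized before warping are interpolated once more during the warp,
so very coarse template grids would blur the gradient; at 1 mm the
gradient (sigma = 50 mm) is vastly oversampled and the choice is
immaterial.

### Deformation fields

Warps are represented as *absolute coordinate lookups*: for every
voxel of the output grid the field stores the source-space coordinate
(mm) to sample, which matches pull-back resampling semantics directly
and sidesteps displacement-field sign/convention ambiguity. The
package never assumes an identity warp implicitly — `warp: identity`
must be stated, or a field supplied. Out-of-bounds samples return 0:
template content outside the head carries no connectivity meaning.

## Streamline propagation

Directions come from the diffusion tensor, interpolated
component-wise (trilinear by default, nearest-voxel optionally):

* **Principal direction (DTI):** the unit eigenvector of the largest
  eigenvalue, sign-aligned with the incoming direction.
* **Tensor deflection (TEND):** `v_out = normalize(D v_in)`. The
  tensor bends, rather than replaces, the incoming direction, which
  makes it robust on low-quality clinical data and lets streamlines
  pass through orthogonal fiber crossings (where the averaged tensor
  is oblate and deflection is nearly neutral) — both behaviors are
  exercised by the phantom tests.

Other direction sources (externally computed FOD peaks, for instance)
plug in through `direction_model(type = "custom")`, a function of
position and incoming direction; masks, termination and perturbation
are then still handled by the package.

Propagation is bidirectional: the initial direction is the principal
eigenvector at the seed, both orientations are marched, and the halves
are concatenated with the seed interior — star-like convergence
patterns around the midbrain need both ends of each trace, and a
bidirectional trace is counted as *one* streamline in the aggregation
sum. Each step moves `alpha` mm (default 1 mm, matched to typical
1.25–2 mm acquisitions) along the model direction after stochastic
perturbation `normalize(v + s*eps)`, `eps ~ N(0, I3)`. The noise
factor `s` controls the exploration/stability trade-off; useful values
run from 0.05 (near-deterministic) to 0.2 (strongly dispersed) and the
package default is the mid-range 0.1.

Termination, per half: leaving the tracking mask (nearest-voxel test),
exhausting the step budget, turning more than the angle threshold in
one step, fractional anisotropy below the floor, or an undefined model
direction. The defaults — 250 steps per half, 60 degrees, FA 0.10 —
are conventional tractography settings, configurable, and recorded in
every map's parameter snapshot. A capped step budget is a pragmatic
guard; no claim is made that real anatomical streamlines are
length-limited.

Degenerate leading eigenspaces (`lambda1 - lambda2 < 1e-9 * trace`)
are resolved by keeping the incoming direction, so deflection through
a balanced crossing degrades gracefully instead of flipping randomly;
at a seed (no incoming direction) degeneracy terminates the streamline
as undefined.

### Seeding and reproducibility

Seeding happens on the *output* grid, which may be finer than the
diffusion grid — this is the super-resolution mechanism (0.5 mm maps
from 1.25 mm data; 1 mm from 2 mm). Starting positions are jittered
uniformly within the output voxel to avoid grid aliasing, and 500
streamlines per voxel is the recommended production default (tight
DTI-like direction fields saturate earlier; the phantom tests use
15–50 for speed). Every (seed-voxel, streamline) pair runs on its own
deterministically derived RNG substream, so maps are bit-reproducible
under a fixed root seed and independent of execution order.

## Display normalization

Color channels must lie in [0, 1] for display, but the aggregation
sum is unbounded and has no natural scale. `normalize_for_display()`
computes per-voxel brightness (the channel sum) over the target
region, divides all channels by its 80th percentile and clips the few
overexposed values to [0, 1]. The percentile is computed by linear
interpolation between order statistics (R's default type 7); the
definition is fixed and documented because different percentile
conventions would change displays subtly. Normalization is
scale-invariant and for-display only: the reproducibility index and
group averaging always consume raw maps.

## Test–retest reproducibility: the icd index

With two scans per subject mapped to a common grid, reproducibility is
summarized by the intraclass distance index

$$icd = 100\% \left(1 - \frac{N \sum_{n} \lVert s_{n1}-s_{n2} \rVert^2}
 {\sum_{j}\sum_{n} \lVert s_{j1}-s_{n2}\rVert^2}\right)$$

where `s_nk` is subject `n`'s map from scan `k` and the squared
Euclidean distance runs over all masked voxels and channels, weighted
equally and without intensity normalization. Identical within-subject
scans with distinct subjects give exactly 100%; a single subject with
distinct scans gives exactly 0%. Two definitional subtleties are kept
as stated rather than "fixed": the denominator's double sum retains
its `j = n` diagonal terms (an `exclude_diagonal` flag exposes the
conventional variant for sensitivity analysis), and the index is not
algebraically confined to be non-negative for adversarial inputs —
negative values are reported as computed. Voxels absent in any map of
a re-scan set are dropped from the shared mask (complete-case
analysis) so every distance compares identical supports.

## What the phantoms emulate — and what they do not

The phantom module replaces real acquisitions with tensor corridors of
known geometry: a straight corridor (optionally tilted in-plane), a
quarter-circle corridor with tangent-aligned tensors, and two
orthogonal corridors whose overlap averages to an oblate tensor
(exercising the degenerate tie-break). Corridor eigenvalues default to
(1.7, 0.3, 0.3) um^2/ms (FA about 0.80, coherent white matter); the
background is isotropic at 0.7 um^2/ms. Voxels are 2 mm by default (a
clinical-scanner analogue; 1.25 mm emulates a high-quality research
acquisition). Color ground truth comes from ramp fields (affine in one
coordinate, hence exactly representable under trilinear interpolation)
and two-end cap fields, for which mid-corridor seeds must accumulate
the two cap colors 1:1 by symmetry.

Re-scan pairs perturb the tensor components directly (Gaussian,
relative scale, PSD re-projection) rather than re-simulating noisy
DWIs: this isolates tracking-and-aggregation reproducibility from
fitting noise, which is validated separately via `simulate_dwi()`
with Rician noise. The synthetic re-scan cohort used in the
acceptance tests has 8 "subjects" (corridors at distinct angles,
−21°…21°), tensor-level re-scan noise of 0.05, 30 seeds per voxel and
a 2 mm-radius spherical target on a common 1 mm grid; with it, the
package reproduces the qualitative finding that near-deterministic
deflection tracking (s = 0.05) yields a far higher icd than strongly
perturbed tracking (s = 0.2).

Phantoms deliberately omit much of real data: no susceptibility
distortion, no partial-volume gray/CSF mixtures, no crossing-angle
continua, no registration error (warps are exact by construction), no
inter-subject anatomical variability beyond corridor pose. Passing
phantom tests therefore demonstrates correctness of the *computation*
— interpolation, propagation, aggregation, the index — not that any
particular clinical acquisition will yield reproducible maps.

## Numerical choices

* Voxel centers map through the affine as `world = A (i, j, k, 1)^T`
  with 0-based indices; grids must be orthogonal (sheared affines are
  rejected at I/O and construction time).
* Trilinear sampling returns 0 outside the convex hull of voxel
  centers; coordinates within 1e-6 voxel units of the boundary are
  snapped onto it so that edge-plane voxel centers are not lost to
  floating-point noise.
* Streamline points enter the aggregation exactly as stepped (spacing
  `alpha`); there is no sub-step resampling, since the sum is defined
  over the streamline's own parametrization.
* Absent (out-of-region) voxels are NaN in float outputs and 0 in
  display exports.
* Tensor fitting is plain ordinary least squares on log-signals with
  post-hoc eigenvalue clamping; it is the standard baseline, exact on
  noiseless data, and not intended to compete with iterative weighted
  or robust fitters.

## Problem sizes used in the shipped validation

The test suite runs phantoms of about `11 x 21 x 11` voxels at 2 mm,
bundles of 15–500 streamlines and cohorts of 8 synthetic subjects;
the Monte-Carlo scaling check uses 300 repeated bundles at 40 and 80
seeds. These sizes were chosen so the full suite completes in well
under a minute of tracking time while each check retains a comfortable
statistical margin (the sqrt(N) ratio test, for instance, has a
sampling error near 5% against a 20% acceptance band).

## Known limitations

* Fiber-orientation-distribution estimation (spherical deconvolution
  variants, global tractography) is out of scope; such direction
  fields enter only through the custom direction-model interface.
* Registration itself is out of scope: deformation fields are
  consumed, never estimated.
* The icd index is reported without inferential machinery (no
  confidence intervals or permutation tests).
* The step-budget and angle-threshold defaults are conventions, not
  fitted quantities; maps in convoluted anatomy are sensitive to them
  and the parameter snapshot should always be reported alongside.
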