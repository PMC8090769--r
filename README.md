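# spectre

Track-weighted color maps for visualizing connectivity patterns inside
small deep-brain target regions — with a reproducibility index and a
fully synthetic validation harness.

## The problem and the method

Stereotactic targets such as the subthalamic nucleus (STN) are nearly
featureless on conventional MRI, yet their internal functional
organization (limbic → associative → motor) is mirrored in their
long-range connectivity. This package makes that organization visible
as color. A smooth color gradient is defined once in template (MNI)
space as a sum of three Gaussians, each feeding one RGB channel,

    c(r) = Σᵢ aᵢ · exp(−|rᵢ − r|² / (2σ²)),   i = 1..3,

(shipped scheme: a₁ = (0.5,0,0) at r₁ = (0,−60,70), a₂ = (0,1,0) at
r₂ = (0,70,0), a₃ = (0,0,1) at r₃ = (0,20,70), σ = 50 mm), warped to
each subject through a dense deformation field, and then aggregated
along diffusion-MRI streamlines: for every voxel r of a target region,
N streamlines are propagated (principal tensor direction, or tensor
deflection — TEND — for robustness on clinical data, with stochastic
direction perturbation) and the warped color field is summed along
them,

    C_k(r) = Σ_f Σ_n c_k(x_n^{r,f}),

with trilinear interpolation at the fractional positions and *no*
length normalization — longer streamlines deliberately contribute
more. Seeding on a grid finer than the diffusion data (500 seeds per
voxel, 0.5 or 1 mm output) yields super-resolved maps. Test–retest
stability is quantified by the intraclass-distance index

    icd = 100% · (1 − N Σₙ ‖s_{n1} − s_{n2}‖² / Σⱼ Σₙ ‖s_{j1} − s_{n2}‖²),

which is 100% when each subject's two scans agree perfectly relative
to between-subject differences. Everything — tensors, colors, warps,
re-scan pairs — can be generated synthetically with known ground
truth, so the whole pipeline is testable without any scan data.

## Worked example

A straight anisotropic corridor with a blue cap at one end and a green
cap at the other; a mid-corridor region must accumulate both colors
symmetrically:

```r
library(spectre)

spec    <- phantom_spec(geometry = "straight", shape = c(11, 21, 11))  # 2 mm voxels
tensors <- make_tensor_phantom(spec)
colors  <- make_cap_colorfield(dim(tensors$mask), tensors$affine)

# 2 mm-radius spherical target at the corridor center, on a 1 mm grid
out_affine <- grid_affine(1)
ij <- expand.grid(i = 0:20, j = 0:40, k = 0:20)
rmask <- array(sqrt((ij$i - 10)^2 + (ij$j - 20)^2 + (ij$k - 10)^2) <= 2,
               c(21, 41, 21))
region <- target_region(rmask, out_affine)

map <- compute_spectre(region, direction_model(tensors, "tend"), colors,
                       tracking_params(noise = 0.1, max_steps = 60, seed = 42),
                       n_seeds = 100)
map
#> <spectre_map> 21 x 41 x 21 grid, 3 channel(s), 33 region voxel(s), un-normalized

round(map$data[11, 21, 11, ], 1)       # (red, green, blue) at the center voxel
#> [1]   0.0 711.8 704.2
```

The center voxel collects no red (no red cap exists), and green and
blue in a 711.8 : 704.2 ≈ 1.011 ratio — the 1 : 1 symmetry expected
from a mid-corridor seed, up to Monte-Carlo noise at 100 streamlines.
The magnitudes are meaningful too: each of the 100 bidirectional
streamlines spends roughly 7 of its 1 mm steps inside each colored
cap, and the sum is not normalized by streamline length.

Reproducibility on a small synthetic cohort (3 corridor "subjects" at
distinct angles, two scans each differing by tensor-level noise),
tracked at a low and a high direction-noise factor:

```r
cohort_icd <- function(s) {
  maps <- lapply(1:3, function(n) {
    spec <- phantom_spec(shape = c(11, 21, 11), angle = (n - 2) * 12, seed = n)
    pair <- make_rescan_pair(make_tensor_phantom(spec), noise = 0.05, seed = n)
    cols <- make_cap_colorfield(spec$shape, grid_affine(2))
    lapply(1:2, function(scan)
      compute_spectre(region, direction_model(pair[[scan]], "tend"), cols,
                      tracking_params(noise = s, max_steps = 60,
                                      seed = 100 * n + scan),
                      n_seeds = 50))
  })
  compute_icd(rescan_set(lapply(maps, `[[`, 1), lapply(maps, `[[`, 2)))$icd
}
cohort_icd(0.05)   #> 57.9  (near-deterministic tracking: subjects stay separable)
cohort_icd(0.2)    #> 18.5  (heavy direction noise erodes reproducibility)
```

Near-deterministic deflection tracking is markedly more reproducible
than strongly perturbed tracking — the qualitative ordering the
package's acceptance suite asserts on an 8-subject cohort.

See `vignettes/track-weighted-color-maps.Rmd` for the model details,
parameter rationale and the limits of what phantom validation shows.

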