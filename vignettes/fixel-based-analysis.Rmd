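---
title: "Fixel-based analysis: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixel-based analysis: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixelr)
```

## The measures

White-matter voxels commonly contain several crossing fibre populations.
A *fixel* is one such population within one voxel, characterised by an
axial unit direction (v and −v are the same orientation) and per-fixel
scalar metrics. `fixelr` computes three complementary measures per fixel.

**Fibre density (FD).** The fibre orientation distribution (FOD) is a
function on the sphere represented in real, even-order spherical
harmonics; each of its lobes corresponds to a distinct fibre population,
and the lobe's integral is proportional to the intra-axonal volume of
axons aligned with it (assuming restricted intra-axonal diffusion,
negligible exchange, and consistent global intensity normalisation and
response function across subjects — all upstream of this package). FD is
that lobe integral, computed by numerical quadrature on a dense
hemisphere mesh.

**Fibre-bundle cross-section (FC).** Spatial normalisation supplies, per
subject, a warp that maps template positions to subject positions (the
pull-back convention). Its local linearisation at a voxel is the Jacobian
matrix J. The determinant of J measures local volume change, but for
white matter only change *perpendicular* to the fibre matters: a longer
bundle has the same number of axons, a wider one does not. Factoring the
stretch along the fixel direction v out of the volume change leaves

$$\mathrm{FC} = \frac{\det J}{\lVert J \hat v \rVert},$$

the area change of the plane perpendicular to the fibre. FC > 1 means
the subject bundle has the larger cross-section. The same quantity can be
derived by rotating J into a fibre-aligned orthonormal frame and
triangularising: with Q = [v, e2, e3] a Gram–Schmidt frame and
R the triangular factor of JQ, the perpendicular-plane area scale is
|r22 r33| = det(J)/‖Jv‖. The package implements the single-step formula
and retains the decomposition as an independent test oracle
(`fc_gram_schmidt_oracle`); the two agree to 1e-9 over random
well-conditioned warps in the test suite.

**FDC.** The elementwise product FD × FC. Summed across a bundle's width,
FDC is invariant to any orientation-preserving warp of the bundle (the
conservation property validated by the phantom below), so group
differences in FDC reflect genuine differences in a pathway's total
intra-axonal cross-sectional content rather than artefacts of spatial
normalisation.

When a warp changes a fixel's surrounding anatomy, the direction itself
must follow: reorientation maps v to Jv/‖Jv‖. In the phantom, template
directions are obtained from the subject direction through the inverse
Jacobian (v_t ∝ J⁻¹ v_s), and FC is evaluated at the template direction —
this is the convention under which a pure shear yields FC = √1.25 > 1 at
every fixel.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `fd_threshold` (`fixels_from_fod`) | 0.10 | FOD integral | template fixel-mask threshold; suppresses spurious small lobes (deconvolution ringing) while keeping genuine secondary populations |
| `max_fixels` | 3 | count | crossing of more than three resolvable populations per voxel is rare at clinical angular resolution |
| `sphere_mesh(level)` | 4 (1281 hemisphere vertices) | — | lobe integrals change by well under 0.5% on refinement to the next level; see mesh tests |
| `max_angle` (`match_fixels`) | 30, boundary inclusive | degrees | candidate subject fixels beyond this angle are considered a different population; the template fixel is zero-filled |
| `n_perm` | 5000 | count | permutation FWE resolution (p-floor 1/(m+1)); tests and examples use 200–1000 for speed |
| `noise_sd` (`make_synthetic_cohort`) | 0.1 | log units | ≈10% between-subject coefficient of variation of FD, a realistic cohort spread |
| phantom `length_vox` × `height_vox`, `width_vox` | 48 × 80, 20 | voxels | see below |
| `smoothing_sigma` | 5 | voxels | removes the mid-line discontinuity of the piecewise-cosine displacement |
| `amplitude_divisor` | 8 | — | cosine displacement amplitude is s_x/8 |
| `step` | 0.1 | voxels | sub-voxel step of the cross-section traverse; halving it changes the sums by <0.5% |
| `edge_frac` | 0.05 | fraction of fd0 | bundle-edge detection threshold, robust to the linear interpolation ramp at the boundary |

## The phantom and what it shows

`make_phantom` builds a straight 2D bundle (one fixel per in-bundle
voxel, FD = 1, oriented along x; 2D grids are 3D with a singleton z axis
and identity behaviour along z throughout the package). Three pull-back
transformations are applied: a scale `[[2,0],[0,1]]` along the fibre, a
shear `[[1,0],[0.5,1]]`, and a non-linear displacement
Δy = ±(s_x/8)·cos(2πx/s_x) (sign following y), Gaussian-smoothed with
σ = 5 voxels and converted to a deformation field before
differentiation. `cross_section_sums` then integrates FD and FDC along
curves perpendicular to the locally interpolated fixel orientation, from
the bundle mid-line outwards in 0.1-voxel steps, at every voxel position
along the length.

The validation asserts: Σ FDC across the width equals the pre-transform
Σ FD at every sampled position within 2%, for all three transformations,
while Σ FD alone is conserved only under the scale (which does not touch
the width). In the continuum this conservation is exact for any
diffeomorphism; the 2% band absorbs discretisation error
(finite-difference Jacobians, bilinear interpolation of FD/FDC and of
directions, and the edge-termination rule).

**Grid dimensions.** The phantom's physics (unit FD, σ = 5 smoothing,
amplitude s_x/8, 0.1 steps) is fixed; its grid is a design choice made
once:

- *Length 48.* The cosine amplitude grows with s_x while the smoothing
  scale is fixed, and the warp stays diffeomorphic only while
  2·A_eff/(σ√(2π)) < 1 at the mid-line. Length 48 (amplitude 6,
  attenuated to ≈4.8 by the smoothing along x) respects that bound;
  substantially longer grids at the same divisor produce a folded warp,
  which the package treats as a hard error rather than something to
  clamp.
- *Width 20, height 80.* The bundle must be wide relative to the voxel
  for the cross-section integrals to be dominated by the bundle rather
  than by the interpolation ramp at its edge (the ramp contributes a
  fixed ~1-voxel-scale uncertainty per edge, so relative accuracy scales
  with width). Twenty voxels across is comfortably within the 2%
  validation band; the height leaves room for the bundle to translate
  and shear without leaving the field of view.
- Cross-sections whose traverse runs into the grid boundary instead of a
  genuine bundle edge (the sheared bundle exits the field of view for
  part of its length) are flagged `complete = FALSE` and excluded by
  default: a clipped column has no defined full width.

## Lobe segmentation

FOD lobes are segmented on the hemisphere mesh by steepest-ascent
watershed: every vertex with positive amplitude walks to its highest
neighbour until it reaches a local maximum; basins draining to the same
maximum form one lobe. Choices a practitioner should know:

- *Trough definition.* Lobe boundaries are watershed ridges, not
  zero-crossings; a zero-crossing rule would be an alternative but cannot
  separate lobes that meet above zero.
- *Ties and plateaus.* Ascent ties break to the lowest vertex index
  (deterministic). Adjacent vertices with exactly equal positive
  amplitude are merged into one lobe — a flat region contains no trough;
  without this a constant (pure l = 0) FOD would fragment into one lobe
  per vertex. The merged lobe's peak is its highest-amplitude member.
- *Negative amplitudes* (constrained spherical deconvolution may leave
  small negative residuals) are clamped to zero and take no part in
  integration.
- *Quadrature weights* are barycentric: each vertex receives one third of
  the spherical area of each incident triangle. These sum to the
  hemisphere area 2π exactly, making the pure-l=0 integral c₀√π exact;
  a spherical Voronoi tessellation would be an equivalent-order
  alternative at more implementation cost.
- *Hemisphere topology.* The mesh is a full icosphere with antipodal
  vertex pairs identified, and adjacency mapped through the
  identification — so watershed basins wrap correctly across the equator
  (axial orientations have no seam).
- *Peak refinement.* The reported lobe direction refines the peak vertex
  by a quadratic fit over its mesh neighbourhood on the tangent plane,
  falling back to the vertex direction when the fit is not an interior
  maximum.

## Statistics

Fixel-wise inference uses an ordinary least-squares GLM per fixel and
controls family-wise error with the max-statistic permutation method:
the observed statistic at each fixel is ranked against the permutation
distribution of the maximum statistic over all fixels, giving
p = (b+1)/(m+1), which is valid (never anti-conservative) at any m and
has p-floor 1/(m+1). Nuisance covariates (design columns with zero
contrast weight) are handled by Freedman–Lane permutation — the standard
scheme: fit the nuisance-only model, permute its residuals, refit the
full model. When n! does not exceed `n_perm` all permutations are
enumerated instead of sampled. Tests are two-sided by default
(`two_sided = FALSE` ranks the signed statistic for directional
hypotheses such as patient < control).

Connectivity-based fixel enhancement (CFE) is deliberately not
reimplemented: its algorithm is defined in prior work, not here. The
`enhance` hook accepts any function of the per-fixel t-statistics, so a
CFE implementation can be dropped into the max-statistic step; the
default is the raw t-statistic. Analyses using the default therefore
trade the sensitivity of connectivity-informed smoothing for complete
independence from a tractogram.

The synthetic cohort generator multiplies template fixel values by a
group effect and lognormal noise (multiplicative noise keeps the metric
positive, matching how density-like quantities vary across subjects). It
emulates between-subject variation and localised group deficits; it does
*not* emulate registration error, fixel mismatches across subjects,
spatially correlated noise, or scanner effects — so passing tests
demonstrate the statistical machinery's calibration and power under
clean correspondence, not robustness to registration failure. The test
suite calibrates the null (empirical FWE over 200 pure-noise replicates
of 20 subjects × 200 fixels at 1000 permutations) and verifies recovery
of a planted d = 3 deficit; these problem sizes were chosen to make the
Monte-Carlo error small relative to the 0.05 nominal level while keeping
the suite quick to run.

## Degenerate inputs and hard errors

- A warp with det(J) ≤ 0 at any in-mask voxel ("folded") is an error,
  never clamped — silently clamping would corrupt group statistics.
- A Jacobian that collapses a fixel direction (‖Jv‖ ≈ 0) is a
  degenerate-warp error.
- Jacobians are computed in physical (mm) coordinates through the image
  affine, so anisotropic voxels are handled; singleton axes of 2D grids
  contribute an identity row and column.
- Fixel directions are stored unit-length; input deviating by more than
  1e-4 is renormalised with a warning, beyond 5% it is rejected.
- FC is analysed raw (no log transform) by default, matching the
  validation experiments; users wanting symmetric treatment of
  expansion/contraction can transform the FC values themselves.
- One subject fixel may serve several template fixels in the same voxel
  (no one-to-one assignment constraint); the alternative — greedy
  bipartite matching — would make matches order-dependent with no clear
  benefit at realistic fixel counts.

## Known limitations

- FOD registration itself is out of scope: warps are consumed as inputs
  (the phantom generates analytic ones).
- No DWI-signal-level simulation: phantom fixels are constructed
  directly.
- The on-disk fixel directory stores float32 values; round trips are
  lossless at that precision, not at double precision.
- FC is a *relative, local* measure of cross-section change under
  normalisation — not an absolute bundle calibre; structures thinner
  than a voxel express cross-section differences as FD change instead
  (partial volume), which is precisely why the combined FDC measure is
  recommended alongside FD and FC.
- Modulation by FC is appropriate only for density-like metrics; do not
  modulate diffusivity- or relaxometry-type fixel metrics.
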