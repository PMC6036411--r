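---
title: "Methods: quantitative registration QA with regqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative registration QA with regqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regqa)
```

`regqa` scores the output of rigid and deformable image registration against
known ground truth: per-axis translation errors against the half-voxel
criterion, rotation-axis misalignment in degrees, landmark target
registration error (TRE) against mean/max tolerances, and contour Dice
coefficients against the 0.8–0.9 acceptance band. This vignette records the
conventions, the numerical choices, and the reasoning behind the places
where the design was genuinely open.

## Coordinate and direction conventions

Everything is DICOM LPS: +x toward patient left, +y posterior, +z superior,
millimetres throughout, angles in degrees at every interface (radians only
internally). Grids are axis-aligned with point = origin + index · spacing;
direction cosines beyond axis-aligned are a declared limitation of the mask
and DVF readers.

Two direction conventions meet in a registration check and most sign
mistakes live at their junction:

* the **physical shift** of a dataset, stated in patient directions
  (Lt/Rt, Ant/Post, Sup/Inf) and converted to an LPS vector by
  `patient_shift_to_dicom()` (Left, Posterior, Superior are the positive
  ends);
* the **registration object's matrix**, which maps the stationary (target)
  frame to the moving frame — opposite to the registration direction. For a
  pure translation, `expected_translation()` therefore negates the LPS shift
  when the *stationary* dataset was the one shifted, and keeps it when the
  *moving* dataset was.

A deformable registration maps target-frame points into the moving frame:
`q = post(pre(p) + d(pre(p)))`, with the optional pre/post rigid transforms
of the DICOM deformable object defaulting to identity. A command-line flag
selecting which point list plays "fixed" inverts point roles; the field
itself is never inverted.

## The rigid rotation model

For a case with known rotations $(\theta_x, \theta_y, \theta_z)$ and a known
shift, the nominal moving-to-stationary matrix is

$$M = \begin{pmatrix} R & t \\ 0 & 1 \end{pmatrix},
\qquad R = R_z(\theta_z)\, R_y(\theta_y)\, R_x(\theta_x),$$

i.e. rotations are applied about Z first, then Y, then X, followed by the
translation. Two conventions here are deliberate and load-bearing:

* **Composition order.** Descriptions of this construction sometimes state
  the product in the opposite order; we validated the order numerically
  against the published worked example for this case (the forward and
  inverted matrices printed to 3 decimals) and only $R_z R_y R_x$ with the
  elementary layouts below reproduces them. The worked numbers are the
  ground truth; `compose_rotations()` defaults to `"zyx"` and exposes an
  `order` argument for software that composes differently.
* **The $R_y$ layout.** The elementary $R_y$ used by the worked example
  places $-\sin\theta$ at row 1, column 3 — the transpose of the common
  textbook form. `rotation_about_axis("y", ...)` implements exactly this
  layout. The two conventions must travel together: mixing the textbook
  $R_y$ into the `"zyx"` product does not reproduce the published matrices.

The inverse used for comparison with the registration object is the exact
rigid inverse $(R^\top, -R^\top t)$ whenever the rotation block is
orthonormal to $10^{-9}$; for blocks re-read from rounded files the full
4×4 solve is used instead. Matrices whose orthonormality defect exceeds
$10^{-3}$ are rejected; smaller defects (typical of values printed to 3–4
decimals) produce a warning and are accepted.

## Rotation-axis misalignment

Per-axis angular errors of a composite 3-D rotation are not well defined
(the decomposition is degenerate), so overall angular misalignment is
measured between rotation axes: the real eigenvector of each 3×3 rotation
block with eigenvalue nearest $+1$, compared through
$\theta = \arccos\lvert u \cdot v \rvert$.

* **Sign.** An eigenvector's sign is solver-dependent, so
  `rotation_axis()` canonicalizes it (largest-magnitude component positive)
  and `axis_misalignment()` takes the absolute dot product; the result lies
  in $[0^\circ, 90^\circ]$ regardless of which solver produced either axis.
* **Degeneracy.** For a (numerically) zero rotation angle — trace within
  $10^{-9}$ radians of the identity's — the axis is undefined. The axis is
  returned as `NA` with a `degenerate` flag, and a flagged axis compares as
  $0^\circ$ with a warning: an identity registration of an identity case
  must not fail QA on an undefined quantity.
* For exactly-orthonormal input the eigen-axis agrees with the skew-part
  axis $(R_{32}-R_{23},\, R_{13}-R_{31},\, R_{21}-R_{12})$ up to sign; the
  test suite checks both routes against each other. The eigen route is kept
  as the implementation because it remains usable for rounded file-read
  matrices and for angles near $180^\circ$.

## Tolerances and boundary semantics

* **Half-voxel criterion** (rigid): axis $i$ passes iff
  $\lvert \Delta_i \rvert \le v_i/2$. The boundary is *inclusive*: "below
  half a voxel" is aspirational wording, and a tie should not fail a
  commissioning test.
* **TRE** (deformable): pass iff mean $< 2$ mm and max $< 5$ mm, *strict*
  inequalities matching the stated wording. Both thresholds are arguments.
* **DSC bands**: below 0.8 fail, 0.8–0.9 acceptable, above 0.9 good;
  configurable edges.
* **SD of TRE.** Published "±1SD" summaries do not state the denominator;
  we default to the sample SD ($n-1$) and expose `sd_type = "population"`.
  At the $n \ge 100$ landmark counts typical of these tests the difference
  is far below reporting precision.
* Reporting precision follows the field's convention: mm and degrees to
  0.01, DSC to 3 decimals.

## DVF interpolation

Exported DVFs are stored at voxel centers, often on a grid coarser than the
image (downsampling factors of 2–4 are common), and landmark positions are
sub-voxel. The interpolation scheme is our documented choice, not a given:
`sample_dvf()` uses **trilinear** interpolation (exact at voxel centers, and
exact everywhere for componentwise-affine fields — the property the test
oracles exploit), with nearest-neighbour available for sensitivity checks.
Points outside the voxel-center hull are a hard error by default
(`policy = "strict"`), because silent clamping hides export bugs; the
`"clamp"` policy, when requested, clamps to the edge, counts the affected
points, and by construction can never produce a value outside the range of
the stored displacements.

## File formats

The rigid registration reader supports two parse modes. For files in the
package's own minimal text registration format the matrix is read from its
declared field (`tag_based`). For any other file — including binary DICOM
REG objects — the raw bytes are scanned for the 16-value slash-separated
row-major ASCII run ending `0/0/0/1` that DICOM embeds (`raw_scan`), which
is exactly how a physicist extracts the matrix with a text editor; the mode
is recorded in the record's provenance, and multiple candidate runs are an
error that lists them rather than a silent first-match. Matrix values are
serialized at 17 significant digits, so write/read round-trips are
bit-exact.

Deformable records use a text header plus a little-endian float32 stream
(the precision DICOM vector grids use; round-trips are exact at float32,
i.e. a relative $2^{-24}$ on each displacement). Masks are NRRD (uint8, raw
or ASCII text encoding) with geometry taken only from `space origin` /
`space directions`. Landmark files are delimited text in either a
millimetre or a voxel-index dialect; the dialect, index base and (for
indices) grid geometry must be declared explicitly — auto-detection is
deliberately refused.

## The synthetic fixture generator

The generator replaces the commissioning phantom datasets with seeded
fixtures whose ground truth is analytic, so that what a test recovers can be
compared with what was injected:

* `gen_rigid_case()` builds the nominal transform for a stated shift and
  rotation and writes a "reported" registration equal to its inverse plus an
  injected error. Translation errors are injected additively and must be
  recovered to $10^{-9}$ mm. Rotation errors are injected by tilting the
  rotation axis by exactly the requested angle about a random perpendicular
  (Rodrigues construction, preserving the rotation angle), so
  `axis_misalignment()` must recover the tilt to $10^{-6}$ degrees.
* `gen_dvf_case()` samples an analytic field (zero, affine, Gaussian bump,
  sinusoid) at voxel centers and stores landmarks with their exact
  analytically-mapped positions. Each manifest carries a conservative
  trilinear error bound $\tfrac{1}{8}\sum_i h_i^2 \max\lvert
  \partial^2 d/\partial x_i^2\rvert$ per component (for the Gaussian bump,
  $\max\lvert\partial^2\rvert \le A/\sigma^2$) plus the float32
  serialization term; fixture landmarks must fall within the bound. The
  affine family's bound is zero, giving an exactness oracle. Defaults — a
  $101\times101\times61$ grid at $2\times2\times2.5$ mm spacing, 100
  landmarks, percent-level affine coefficients, an 8 mm / $\sigma$ = 30 mm
  bump — emulate a thoracic DVF export at a typical downsampled resolution
  and breathing-scale deformation magnitudes.
* `gen_mask_pair()` rasterizes sphere or box pairs with the *voxel-center
  inside* occupancy rule (the simplest unbiased rule, and the one whose
  error bounds are computable). Boxes commensurate with the voxel lattice
  rasterize exactly; sphere manifests carry a surface-shell tolerance. The
  canonical pair — unit spheres one radius apart — has the closed-form lens
  overlap $\pi(4r+d)(2r-d)^2/12$ and DSC exactly $5/16$, which the masks
  approach as the voxel shrinks.

What the fixtures do *not* emulate: image intensities (registration itself
is out of scope), realistic anatomical shapes, DVFs that are non-invertible
or folded, and observer variability in contouring. Passing fixture tests
therefore demonstrates that the *measurement* pipeline is correct — not that
any registration algorithm is accurate, and not that contour-based and
landmark-based conclusions will agree on clinical data (published
evaluations find they often do not).

## Problem sizes and determinism

The test suite runs entirely on generated data: property checks use up to
1000 random rotation triples and 100-seed file round-trips; DVF oracles use
$21^3$–$41^3$ grids with 40–100 landmarks; the sphere-pair Dice convergence
uses voxel sizes 0.2, 0.12, 0.05 (and 0.02 for the closed-form endpoint),
the finest grid holding about 1.7M voxels per mask. Every random draw sits
behind an explicit seed; bundle regeneration with the same seed is
bit-identical (hash-compared in the tests).

## Known limitations

* Axis-aligned geometry only; no direction-cosine support in NRRD or DVF
  grids, and no resampling between mismatched mask grids — masks must be
  produced on a common grid upstream, because any implicit resampling
  policy would silently change the DSC.
* No DVF inversion, Jacobian/folding analysis, or dose warping.
* No DICOM RT Structure Set polygon handling: binary masks are the
  contract.
* No general Euler-angle decomposition of an arbitrary rotation — only the
  axis comparison, which is the well-defined quantity.
* Surface-distance metrics (Hausdorff, mean distance to agreement) are
  excluded by design; DSC together with structure volume is used as the
  practical contour metric.
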