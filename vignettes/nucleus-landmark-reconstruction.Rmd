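---
title: "Nucleus landmark-based 3D reconstruction of serial histology sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleus landmark-based 3D reconstruction of serial histology sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brightfield histology of microvasculature gives sub-micrometre in-plane
resolution but no 3D context: a 5 µm section shows vessel cross-sections
whose connectivity, inclination and true diameter cannot be inferred from
2D. Stacking serial sections back into a volume requires registering each
section to its neighbour and composing the N − 1 pairwise transforms.

The danger in pairwise registration is the *banana-into-cylinder* artifact.
Any method that optimizes the pairwise alignment of large, salient
structures (a vessel cross-section, a muscle fascicle) snaps those
structures onto each other from section to section. A vessel running
obliquely through the block — whose cross-sections *should* drift laterally
by `thickness × tan(inclination)` per section — is thereby straightened
into a section-orthogonal cylinder. The pairwise residual looks excellent;
the composed geometry is wrong, and the error accumulates monotonically
through the stack.

`histo3d` implements a registration cascade built on landmarks that cannot
carry this orientation bias: cell nuclei bisected by the microtome blade.
Nuclei are ≈ 5 µm across, roughly spherical, and abundant; a bisected
nucleus leaves its two halves at homologous positions on exactly two
adjacent sections, and the centroid-to-centroid vectors of many bisected
nuclei have no shared directional bias that a composition of transforms
could amplify.

## The pipeline

For each adjacent pair (fixed section k, moving section k + 1):

1. **Coarse initialization.** Both images are downsampled to about
   172 × 264 pixels (bilinear), converted to grayscale by unweighted RGB
   averaging, and aligned rigidly by minimizing the mean squared intensity
   difference (MSE) over the overlap with a regular-step gradient descent
   (scales 10² rotation / 10⁻² translation, step lengths 4 → 0.1). Both
   refinement branches consume this same initialization.
2. **Nucleus landmark branch** (the method of interest).
   - *Segmentation*: pixels with green channel < 80 % of 255; 8-connected
     components with area 6–160 µm² become landmarks at their centroids.
   - *Debris rejection*: a component whose surrounding ring (5 µm disk
     dilation minus the component) has mean green > 95 % of 255 **and**
     SD < 4 % of 255 sits on bare glass and is discarded.
   - *Block-matching correspondence*: for each landmark p on section k,
     candidates are landmarks on section k + 1 whose init-mapped centroids
     lie within T = 100 µm of p; each candidate is scored by the MSE
     between the 250 µm square green-channel neighborhoods of p and q,
     window/leveled at 14/235 to stretch the near-white tissue band to full
     contrast; the smallest MSE wins.
   - *Selection*: only the best-scoring 100 correspondences per pair are
     retained — most nuclei are *not* bisected, and the score gap between a
     true bisected pair (same tissue, same neighborhood) and a spurious one
     is what makes the selection work.
   - *Fit*: closed-form least squares on the selected centroid pairs —
     rigid (SVD Procrustes, reflection guarded to det = +1) and optionally
     affine (ordinary least squares; the affine fit reuses the rigid fit's
     correspondences) — composed with the initialization.
3. **Intensity branch** (the conventional comparator): the same MSE
   optimizer run at 4 µm/px, rigid then affine, with refinement step
   lengths 0.01 → 0.001.

Pairwise transforms are composed into cumulative transforms anchored at
section 1 (the untransformed base), and the full-resolution RGB sections
are pull-warped (bilinear, white fill) onto the union bounding grid and
stacked at the section thickness into a multipage TIFF volume with a JSON
voxel-spacing sidecar.

All geometry is computed in physical micrometres (origin at the centre of
pixel (1, 1), x along columns, y along rows), so every threshold above is
resolution-independent.

## Evaluation framework

- **Pairwise error**: post-registration Euclidean distance between
  homologous landmark pairs on adjacent sections — TRE when the pairs were
  withheld from the fit, FRE when they defined it. FRE is the optimistic
  bound; leave-one-out cross-validation (`loocv_tre`) sits between them.
- **Reference reconstruction**: a surrogate ideal chain fit (affine by
  default) to verified, withheld landmark pairs.
- **Accumulated error**: each reference landmark mapped to the section-1
  frame through both the algorithm's and the reference cumulative chains;
  the distance between the two images of the landmark captures error
  propagation that pairwise errors hide. Section 1 is zero by construction.
- **Distribution summaries**: median ± IQR with a rank-based 95 % CI on the
  median (sorted-sample ranks n/2 ± 1.96·√n/2, rounded to the nearest rank
  and clamped); per-section maxima with mean ± SD. Paired comparisons use
  the Wilcoxon signed-rank test after a Kolmogorov–Smirnov normality screen
  (reported, never used to switch tests — registration errors are reliably
  non-normal).
- **Metric-landscape sweep**: full-resolution MSE evaluated at ±20 µm in
  0.5 µm steps (81 samples per axis) around a given transform, reporting
  the displacement of the MSE minimum — used to ask whether an ideal
  intensity optimizer could even agree with the landmark solution.
- **Non-parametric prediction bound**: the sample maximum bounds the
  P % prediction interval with P = 100·(N − 1)/(N + 1).

## The phantom

`generate_phantom()` is first-class, tested code, not a fixture: it renders
serial sections with the statistical and optical structure the method
assumes, plus exact ground truth for every stage.

- **Geometry**: nuclei are spheres placed uniformly in the 3D tissue slab;
  each section renders the largest circle of the sphere–slab intersection.
  Diameters are Normal(5, 0.4) µm truncated to (3.6, 4.98) µm — just below
  the 5 µm section thickness, so a nucleus is bisected by at most one
  cutting plane and a bisected nucleus appears on exactly two sections with
  *identical* world (x, y) centroids: exact homology for free. The vessel
  is a brown annulus (white lumen) around a straight 3D centerline at a
  known inclination.
- **Optics**: background is slide white (255); tissue is a light pink whose
  green level (≈ 91 % of 255) sits strictly between the nucleus color
  threshold (80 %) and the slide-background criterion (95 %); nuclei are
  hematoxylin-blue (green ≈ 43 %); vessel walls DAB-brown. The tissue
  carries a smooth random texture (correlation length 60 µm — the scale of
  muscle fibres — amplitude 8 shared across sections plus 1.5 per section)
  centred inside the 14/235 window/level band, so block-matching
  neighborhoods have usable, section-correlated contrast; pixel noise
  (SD 3) is added after warping.
- **Perturbations**: each section (except section 1, the anchored base)
  receives an independent uniform rigid draw (defaults |t| ≤ 50 µm,
  |θ| ≤ 5°, the jitter scale the pipeline is designed for) and optionally a
  shear/scale deviation of the linear part; the rendered world image is
  warped by the perturbation's inverse so registration must recover it.
  Draws are independent — no drift — so any accumulated-error growth is
  attributable to the registration, not the phantom.
- **Splits**: bisected nuclei are split 50/50 into a registration-visible
  and a withheld *reference* split; all reported TREs use the reference
  split.

What the phantom does **not** emulate: real tissue deformation (folds,
tears, stretch — the affine model's residual on real tissue), staining
variability between sections, touching-nuclei clutter, and anisotropic
chromatin texture inside nuclei. Passing tests therefore demonstrate that
the algorithmic chain is correct and unbiased under its own model
assumptions, not that real-tissue error will be as small; on real tissue
the dominant error term is unmodelled deformation.

## Numerical and design choices

- Warping is backward (pull) with bilinear interpolation and white fill;
  MSE is averaged over the overlap only (no correction term as the overlap
  shrinks — a known limitation shared with the plain metric definition).
- The optimizer is a regular-step descent: step along the scale-normalized
  negative gradient; on a direction reversal *or* a metric increase the
  step is halved (relaxation 0.5), and candidate steps that would increase
  the MSE are rejected, so the accepted metric trace is non-increasing.
  Convergence when the step falls below the minimum; iteration cap 200.
  Gradients are central finite differences whose perturbation is about one
  pixel, annealed with the step length (floored at 5 % of a pixel): wide
  differences average the pixel-scale interpolation/noise ripple of a
  bilinear MSE landscape, fine differences sharpen convergence.
- Rotation is parameterized about the image centre (decouples rotation from
  translation); affine parameter scales mirror the rigid convention
  (matrix 10², translation 10⁻²).
- Rigid fits force det = +1 (a reflection can otherwise win the
  unconstrained Procrustes problem on noisy pairs).
- Candidate gating is inclusive (distance ≤ T) and applied after mapping
  through the coarse initialization — without that mapping the 100 µm ball
  might not contain the true partner at all.
- Correspondence runs one way (earlier section seeks its match on the later
  one) and many-to-one matches are allowed; a mutual-best filter exists but
  is off by default. Ties in the best-k selection break by
  (score, y, x) for determinism.
- Component connectivity is 8-connected; CI rank rounding is
  nearest-integer, clamped to [1, n]; Wilcoxon zero differences are
  discarded (standard signed-rank convention).
- Degenerate inputs fail loudly: coincident points (rigid fit), collinear
  configurations (affine fit), empty overlap (MSE), unregistrable section
  pairs (< 2 correspondences), degenerate LOOCV folds are reported missing
  rather than fabricated.

## Problem sizes used in the shipped checks

The package's own end-to-end checks run on phantoms chosen to exercise the
stated operating conditions at desk scale: 2 × 2 mm section pairs at
1 µm/px (≈ 200 bisected nuclei per cutting plane, perturbations up to
50 µm / 5°, shear/scale up to 5 %) for pairwise recovery, and a 10-section
1.3 × 1.3 mm stack with a 30°-inclined vessel for the geometry-preservation
comparison against a deliberately naive vessel-centroid baseline. Under
those conditions the held-out TRE of the nucleus pipeline is well under
2 µm, the affine fit recovers perturbation matrix entries to ≈ 10⁻³, and
the reconstructed vessel inclination stays within a few degrees of truth
while the naive baseline collapses it toward 0° — the banana-into-cylinder
failure made visible. The statistics layer is checked for calibration
(≈ 95 % empirical CI coverage, exact (N − 1)/(N + 1) prediction level,
LOOCV ≥ FRE optimism ordering). The exact numbers are computed, not quoted:
see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Known limitations

- Transforms are rigid/affine only; real section deformation is non-affine
  and bounds achievable accuracy on real tissue.
- The gating radius T = 100 µm is brittle by construction: if the coarse
  initialization errs by more than T anywhere, the true partner is outside
  every candidate set. T should be grown to cover the observed
  initialization error when porting to other tissues.
- Missing or damaged sections are not modelled; section indices must be
  contiguous.
- Only the MSE similarity metric is implemented (mono-modality serial
  sections with consistent staining); whole-slide pyramid formats and stain
  unmixing are out of scope.
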