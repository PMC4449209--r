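# histo3d

Fully automatic 3D reconstruction of serial brightfield histology sections,
built for microvasculature analysis where *geometry* — vessel inclination,
tortuosity, true diameter — must survive the reconstruction, not just
topology.

## The problem and the method

A paraffin block is cut into 5 µm serial sections, each scanned at
0.25 µm/px. Reassembling the volume means registering every section to its
neighbour and composing the N − 1 pairwise 2D transforms. Conventional
intensity-based registration optimizes the pairwise alignment of large,
salient structures — and thereby straightens every obliquely oriented vessel
into a section-orthogonal cylinder (the "banana-into-cylinder" artifact): an
oblique vessel's cross-sections *should* drift by `thickness · tan θ` per
section, but snapping them onto each other zeroes that drift, and the error
compounds silently through the stack.

`histo3d` instead registers on **bisected nuclei**: cell nuclei (≈ 5 µm, the
section thickness) cut by the microtome blade, whose halves appear at
homologous positions on exactly two adjacent sections and carry no
orientation bias. The cascade per adjacent pair (fixed section *I*, moving
section *J*):

1. **Coarse init** — low-resolution (≈ 172 × 264 px) grayscale rigid
   registration minimizing MSE with a regular-step gradient descent
   (parameter scales 10² / 10⁻², steps 4 → 0.1).
2. **Nucleus landmarks** — segment hematoxylin-stained nuclei (green channel
   < 80 % of 255, 8-connected area 6–160 µm²), reject slide debris (ring
   from a 5 µm dilation with mean green > 95 % and SD < 4 %), and take
   component centroids as landmarks *p*.
3. **Block-matching correspondence** —

       p' = argmin_{q : ‖init(q) − p‖ ≤ T} MSE( I(p), J(q) ),  T = 100 µm

   where `I(p)`, `J(q)` are 250 µm square green-channel neighborhoods,
   window/leveled at 14/235. Only the best (smallest-MSE) 100 pairs per
   section pair are kept — most nuclei are not bisected.
4. **Closed-form fit** — least-squares rigid (SVD Procrustes, det = +1
   enforced) and/or affine transform on the selected centroid pairs,
   composed with the initialization; pairwise transforms compose into
   cumulative transforms anchored at section 1, and the RGB sections are
   warped (bilinear, white fill) onto a union grid and stacked into a
   multipage TIFF volume (voxel spacing e.g. 0.25 × 0.25 × 5 µm in a JSON
   sidecar).

A complete evaluation layer measures pairwise and accumulated target/fiducial
registration error (TRE/FRE) against a reference reconstruction built from
withheld verified landmark pairs, with LOOCV, rank-based non-parametric
CIs on medians (ranks n/2 ± 1.96·√n/2), Wilcoxon signed-rank comparisons,
MSE-landscape sweeps (±20 µm at 0.5 µm), and (N − 1)/(N + 1) prediction
bounds. A synthetic serial-section phantom generator provides exact ground
truth (transforms, homologous nucleus pairs, vessel centerlines) for every
stage.

## Worked example

```r
library(histo3d)

# simulate a 2-section serial pair: 1 x 1 mm at 1 um/px, 5 um sections,
# known rigid perturbation (|t| <= 50 um, |theta| <= 5 deg)
spec <- phantom_spec(n_sections = 2, width_um = 1000, height_um = 1000,
                     nucleus_density_mm2 = 200, seed = 42)
ph <- generate_phantom(spec)

# full nucleus-landmark registration of section 2 onto section 1
rec <- reconstruct(ph$stack, method = "nucleus_rigid", config = list(top_k = 80))
rec$chain$pairwise[[1]]
#> <rigid 2D transform>
#>   matrix: [0.997595 -0.0693188; 0.0693188 0.997595]
#>   translation (um): (79.3683, -55.8811)

# held-out accuracy: TRE on the withheld reference landmark split
refs <- ground_truth_pairs(ph, "reference")
tre <- pairwise_error(rec$chain$pairwise[[1]], refs$pairs[[1]])
summarize_errors(tre)
#> <error report: n = 54, median 1.19 um, IQR 0.911, 95% CI [0.873, 1.55]>
```

The recovered transform (a −3.97° rotation plus translation, mapping
section-2 into section-1 coordinates) reproduces the phantom's hidden
perturbation: the median distance between where the algorithm places a
*withheld* bisected nucleus and where it truly belongs is 1.19 µm — about a
quarter of a nucleus diameter — with the whole 95 % CI under 2 µm.

For volumes: `render_volume(ph$stack, rec)` then `write_volume(vol,
"volume.tiff")`. A thin CLI over these functions ships in
`inst/cli/histo3d.R` (subcommands `phantom`, `reconstruct`, `evaluate`;
YAML configs).

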