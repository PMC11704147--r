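---
title: "Methods: phantom-based OCT-A vessel morphometry and dilation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based OCT-A vessel morphometry and dilation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`octava` implements a complete analysis chain for label-free OCT angiography
(OCT-A) of cortical microvessels: angiogram computation from repeated B-scan
amplitude stacks, surface-referenced volume preparation, vessel segmentation
and branch-graph extraction, Gaussian-FWHM diametry, longitudinal branch
tracking over a two-dose focused-ultrasound (FUS) timeline, and the group
statistics of a sonication-evoked dilation study. Because such studies rarely
deposit raw volumes, the package ships a ground-truthed synthetic phantom so
every stage is testable end to end, and headline group results are framed as
parameter-recovery experiments: configure a known dilation, run the full
pipeline, and check that it reports the configured effect.

This vignette explains the model behind each stage, the tunable parameters
with their defaults and units, the numerical choices, and what the phantom
does and does not emulate.

## The angiography model

OCT-A derives flow contrast from the temporal decorrelation of backscattered
amplitude between repeated B-scans at the same position: moving red blood
cells scramble the speckle pattern inside perfused lumina while static tissue
keeps its speckle realization. With band-limited amplitudes $A_{mn}$ (band
$m$ of $M$, repeat $n$ of $N$), the split-spectrum amplitude decorrelation is

$$D = 1 - \frac{1}{N-1}\frac{1}{M}\sum_{n=1}^{N-1}\sum_{m=1}^{M}
\frac{A_{mn}A_{m,n+1}}{\left(A_{mn}^2 + A_{m,n+1}^2\right)/2},$$

which is 0 for identical nonzero amplitudes, grows toward 1 for independent
speckle, and is invariant under global amplitude scaling. Pixel pairs with
zero amplitude are defined as perfectly correlated (masked to $D = 0$)
to avoid 0/0.

`register_frames()` aligns repeats by phase correlation with local
upsampled-DFT refinement (default shift resolution 0.05 px).
`split_spectrum()` approximates spectral splitting when only amplitude
images exist: each frame's axial Fourier spectrum is multiplied by
one-sided (analytic-signal) Gaussian windows whose centers tile the axial
frequency axis — the complex band-limited signal's modulus is then a smooth
band amplitude. The window count ($M = 4$) and fractional overlap (0.5) are
configurable; the acquisition parameters of any given instrument are not
inferable from amplitude data, so these are declared defaults, not
estimates. One property of true source-spectrum splitting cannot be
reproduced by this surrogate: real spectral bands carry partly independent
speckle realizations, which is what makes band-averaged decorrelation less
noisy. The package therefore asserts that variance reduction at the level of
`decorrelate()` (given band-diverse amplitudes) rather than of the
amplitude-only surrogate.

## The phantom

`phantom_spec()` describes a tissue block (default 600 × 600 µm lateral by
400 µm deep at 2 µm isotropic voxels, with a 60-µm air gap above the
surface) populated by straight cylindrical vessels in three diameter
classes. Voxel values live on the decorrelation scale $[0, 1]$:

* **Vessels** are tubes with a Gaussian radial intensity profile whose
  *full width at half maximum equals the true diameter* (centerline level
  0.6), so the operational diameter definition used by the diametry stage is
  exact on noiseless phantoms.
* **Extravascular tissue** carries a decorrelation floor of 0.06.
* **Speckle** is multiplicative lognormal noise with mean 1 and CV 0.15 by
  default. The rationale: phantom voxels model the *angiogram* — the output
  of split-spectrum averaging — not raw amplitude speckle. Fully developed
  speckle has amplitude CV ≈ 0.52; averaging over $M = 4$ bands ×
  $(N-1) = 3$ repeat pairs reduces it by about $\sqrt{12}$ to ≈ 0.15.
* **Projection tails**: multiple scattering smears angiographic signal
  axially below each vessel. The phantom models this as a floor equal to
  `tail_strength` (default 0.3) times the running maximum of the vessel
  intensity above, decaying with an e-folding depth `tail_decay_um`
  (default 30 µm). Tails never exceed the parent lumen intensity.
* **Surface tilt** (default 2°) shears A-lines along the fast axis at
  nearest-voxel resolution, emulating a brain surface that is not
  perpendicular to the beam.

Class populations: the capillary class draws true diameters from a lognormal
truncated to [5, 15) µm whose parameters are calibrated so the truncated
mean and SD equal the configured 6.2 and 1.3 µm — the published capillary
statistics describe an observed, resolution-floor-limited population, so the
phantom reproduces that population directly. The 15–20 µm class is uniform;
the >20 µm class is a truncated lognormal (mean 30, SD 9, support 20–48 µm).
Depths follow per-class Beta laws with large vessels weighted toward the
surface, as cortical angiograms show. Default counts are 2 large, 3 medium
and 50 small vessels per 600 × 600 µm patch, chosen to match the vessel area
coverage (~20–25 %) visible in published 1-mm² cortical en-face angiograms;
denser scenes produce blended cross-sections that no diametry can resolve.
Vessels are placed with at least a three-diameter in-domain chord so no
vessel is an unmeasurable corner stump.

`build_frame_stack()` emulates the repeated-B-scan acquisition for the
angiograph module: static voxels share one speckle realization across
repeats, while a configurable fraction of intravascular voxels has its
speckle redrawn each repeat; known subpixel inter-frame drifts can be
embedded and are recorded in the metadata.

`study_plan()` freezes one vessel geometry per animal and scales each
branch's diameter at every timepoint by its class factor times an
animal-level lognormal-free multiplicative perturbation (SD
`inter_animal_sd`), plus a rigid lateral drift of up to 5 µm between
timepoints to exercise co-registration. The preset scenarios encode the
published group trajectories: low intensity (capillary factors
1.17/1.23/1.27 at the three post-dose timepoints, 3 % between-animal SD),
high intensity (1.27/1.30/1.32, 8 % SD), and sham (all factors 1, no
between-animal effect SD, so sham truth is exactly null).

What the phantom does **not** emulate: vessel curvature and branching
trees (only straight segments), flow-speed contrast, PSF anisotropy
(2.48 × 3.48 µm in the modeled instrument vs. 2 µm isotropic voxels here),
bulk-motion artifacts, and spatially correlated speckle. Passing tests
therefore demonstrate correctness of the *algorithms* under controlled
conditions, not instrument-level performance on real data.

## Surface referencing

`detect_surface()` finds, per A-line, the first axial voxel whose axially
smoothed intensity exceeds a threshold; the default rule applies Otsu's
method to log-scaled intensities, which separates the empty gap above the
brain from the tissue speckle floor even where superficial vessels are
sparse. Undetected lines (bright-vessel shadows, etc.) are filled by 2D
median interpolation; more than 50 % undetected lines is an error.
`detilt()` fits a least-squares plane to the surface map and shifts every
A-line axially so the plane maps to constant depth. Shifts are applied at
nearest-voxel resolution (the 2-µm axial pitch), leaving a ≤1-µm residual —
well under the 5-µm depth tolerance relevant to depth attribution — and
making zero-tilt volumes pass through bit-identically. After flattening,
depth means "µm below the cortical surface", en-face projections
(`project_enface()`, maximum by default) use half-open slabs `[lo, hi)`,
and `bin_axially()` produces contiguous 25-µm analysis slabs over the
0–400 µm analysis depth (aggregated to 50-µm bins for depth-resolved
reporting).

## Segmentation and the branch graph

`segment_enface()` binarizes the (lightly Gaussian-smoothed, σ = 1 px)
en-face image. The default mask is the union of two Otsu pathways: the
white top-hat band (6.7-µm disc element) captures capillary-scale structure
riding on haze, while the raw-image pathway captures vessels wider than the
top-hat element, whose interiors the top-hat suppresses by construction.
One shared, configurable rule covers both vessel scales. Smoothing is used
*only* for mask formation; diameters are always measured on the raw
en-face image. Components smaller than a 5-µm disc are removed.

`skeletonize_and_graph()` thins the mask (Zhang–Suen with a
connectivity-preserving cleanup to a minimal 8-connected, 1-px skeleton),
splits it into junction-to-junction/junction-to-end branches, prunes
branches shorter than 10 µm (terminal spurs and crossing fragments), and
estimates each branch's width from the distance transform. Two artifact
filters reflect how skeletons behave on real masks: a centerline lying
mostly inside the lumen of a ≥1.6× wider branch is dropped (crossing-induced
edge path), and later, a branch whose FWHM disagrees with its mask width by
more than a factor ~3 is flagged unmeasurable. Branch diameters classify
into `<15`, `15-20` (half-open) and `>20` µm; branches measuring below the
5-µm inclusion floor are excluded entirely.

## Diametry

`place_cross_sections()` lays sampling lines perpendicular to the locally
smoothed centerline every 5 µm (≈15 lines on the shortest measurable
branches), with length max(4 × width estimate, 20 µm); lines within one
diameter of a junction end are skipped because they sample the joining
vessels' overlapping lumina. Profiles are sampled by bilinear interpolation
at 1-µm steps and fitted with a Gaussian plus constant offset
(Levenberg–Marquardt with analytic Jacobian; the width is initialized from
the direct half-maximum crossing). The diameter is
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$.

Two numerical choices matter here:

* **Core-restricted fitting.** A maximum projection composes vessel signal
  and background by *maximum*, so profile tails are clipped flat at the
  background floor and carry no width information; fitting them with an
  additive-offset model biases σ low by ~10 %. The fit therefore uses the
  contiguous profile core above (local baseline + 25 % of amplitude), where
  the baseline is a low quantile of the window (robust to neighbouring
  vessels). On exact additive Gaussians any such subset still recovers the
  parameters exactly, so the noiseless closed-form checks are unaffected.
* **Robust branch average.** A cross-section is accepted if the fit reaches
  R² ≥ 0.5, its center lies in the middle half of the line, its width is
  plausible against the mask width, and the fitted Gaussian is the dominant
  structure in the window (no residual hump comparable to the fitted
  amplitude — blended profiles are rejected, not mis-measured). Under
  multiplicative speckle the per-line FWHM distribution is right-skewed,
  so the branch diameter is the *median* of accepted FWHMs (the mean reads
  ~10 % high on wide vessels); `diam_params(avg = "mean")` restores the
  plain mean. A branch with less than half its lines accepted is flagged
  unmeasurable.

No PSF deconvolution is attempted: the FWHM of the intensity profile *is*
the operational diameter, consistent with a 5-µm inclusion floor that
acknowledges resolution-limited broadening of the smallest vessels.

## Longitudinal tracking and normalization

`coregister_timepoints()` estimates the rigid lateral drift of each later
en-face image onto baseline by subpixel phase correlation (identity with a
warning if the peak is below confidence 0.1; matched angiograms score
>0.6, unrelated images <0.05). `match_branches()` then greedily matches
baseline branches one-to-one to drift-corrected later branches by centerline
overlap (fraction of baseline points within 5 µm), requiring ≥50 % overlap
— with a containment fallback for candidates lying almost entirely on the
baseline centerline, since a later segmentation may split a baseline branch
into pieces that individually miss the floor — and ties broken by overlap
then diameter difference; matching is purely geometric, so a dilated vessel
maps onto itself. One identity gate guards
the geometry: candidates whose diameters disagree by more than a factor 2
are rejected, because a short junction-bracketed fragment of a wide vessel
is geometrically promiscuous and can otherwise lock onto a crossing
capillary; the gate is generous against any plausible physiological change
(≤1.32× here). Branch identity and
diameter class are frozen at baseline ("pre-FUS"), so a dilating 14-µm
vessel does not migrate classes mid-study; normalized diameters are
`diameter / pre-diameter` (exactly 1 at baseline). Branches unmatched at a
given timepoint are analyzed where present (a complete-case analysis is a
trivial filter on the track table). The unit of analysis is the animal:
per-animal means of normalized diameters per class and timepoint feed the
group statistics, matching a design whose paired tests compare individual
animals.

## Group statistics

* `paired_t()` — paired two-tailed Student's t on per-animal values
  (via `stats::t.test`; identical vectors give t = 0, p = 1; a constant
  nonzero difference reports `NA` with a note).
* `anova_lsd()` — two-way ANOVA (`condition × timepoint`, `stats::aov`)
  with Fisher's Least Significant Difference: unadjusted pairwise t
  statistics between cell means using the pooled residual mean square and
  its degrees of freedom (the classical definition; deliberately no
  multiplicity adjustment).
* `mannwhitney_depth()` — Mann–Whitney–Wilcoxon for depth-resolved
  branch-level comparisons: exact when the combined sample is ≤20 without
  ties, otherwise the tie-corrected normal approximation
  (`stats::wilcox.test`).
* `build_table1()` — the class × condition summary: baseline diameters
  summarized across *branches* (hence large SDs for pooled classes),
  normalized post-dose diameters summarized across *animals*, plus the
  paired t of the first post-dose timepoint against baseline. This mixed
  convention mirrors how such tables are reported.
* `depth_report()` — 50-µm depth bins with per-bin distributions, medians,
  quartiles, counts and Mann–Whitney p (bins with <3 branches on either
  side report `NA` but keep counts). Branches, not animals, are the units
  here, as the per-bin branch counts imply.

`simulate_track_table()` provides a branch-table-level fast path (no image
rendering) for calibration experiments; its per-branch measurement CV of
0.02 reflects the residual uncertainty of a branch mean after averaging
~15–40 cross-sections. The type-I error of the paired t under the sham
scenario is checked against the nominal 5 % with this path.

## Problem sizes and determinism

Desk-scale experiments use the reduced 600 × 600 × 400 µm domain (300 × 300
× 230 voxels including the air gap) with 10 animals and 4 timepoints per
study; one full study simulates and analyzes in minutes on a single core,
with the rendering hot loops (tube rasterization, projection tails, speckle)
implemented in C++. All randomness derives from a root seed through a
counter scheme (`animal × stage` sub-seeds below 2³¹), so identical seeds
give byte-identical phantoms and adding animals never perturbs earlier
ones. The acceptance script (`scripts/acceptance.R`) re-runs the low
intensity parameter-recovery study from scratch at exactly these sizes.

## Known limitations

* Straight-segment geometry: no curvature, no true bifurcation trees; the
  branch graph still exercises junctions via crossings.
* The amplitude-only split-spectrum surrogate cannot create band-independent
  speckle (see above).
* Nearest-voxel de-tilt resampling (≤1 µm residual) rather than sub-voxel
  interpolation.
* The 5-µm inclusion floor plus measurement noise slightly truncates the
  smallest capillaries' denominators in normalized ratios, a selection
  effect shared with any floor-limited diametry.
* Because diameter classes are assigned from noisy baseline measurements,
  one-sided classes regress toward the mean: the >20 µm class reads a few
  percent below 1 even under a sham scenario. Published sham tables from
  comparable designs show the same signature; it is a property of the
  design, not a pipeline defect.
* Depth attribution inherits projection-tail confusion by design; the tail
  artifact is modeled but not corrected (consistent with treating its
  removal as out of scope).
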