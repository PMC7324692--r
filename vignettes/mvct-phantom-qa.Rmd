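---
title: "Automated MVCT phantom QA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated MVCT phantom QA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvctqa)
```

## The problem

Helical tomotherapy units (TomoTherapy, Radixact) image patients daily with
their own treatment beam — mega-voltage CT (MVCT). Because image-guided
setup corrections inherit any defect of these images, medical physics
performs a monthly image QA on a cylindrical water-equivalent "cheese"
phantom: 30 cm diameter, 18 cm long, with embedded high-density fiducial
markers, 20 peripheral plug holes for density plugs, and a drilled
resolution plug. TG-148 defines what to check and with what tolerances, but
not *how* to measure it; done by hand the analysis is slow and
analyst-dependent. `mvctqa` automates the four image tests end to end:

1. **Geometric distortion** — marker-to-marker distances in the transaxial
   plane and a marker-to-surface distance longitudinally, compared with
   baseline within 1 mm (SRS/SBRT) or 2 mm.
2. **Uniformity** — largest difference between the mean HU of a 10 mm
   centre ROI and four cardinal periphery ROIs; < 25 HU when the images
   feed dose calculation.
3. **Noise** — sigma-CT of the centre ROIs; informational (typical MVCT
   values run ~50–70 HU at acceptance-era dose settings, though individual
   machines may sit well below this band).
4. **Contrast** — mean HU of each inserted density plug compared with the
   nearest baseline HU, within 30 HU (water-like) or 50 HU.
5. **Spatial resolution** — deliberately *not* automated beyond
   localization and windowing: TG-148's criterion (1.6 mm holes visible)
   is visual, so the package finds and windows the plug and records the
   inspector's verdict verbatim.

## Pipeline

A DICOM series folder is read into a calibrated HU volume: slices are
sorted by `InstanceNumber` (falling back to slice position with a warning),
checked for a single series and a single geometry, and converted to HU with
`RescaleSlope`/`RescaleIntercept` (missing tags are treated as slope 1,
intercept 0, with a warning). The axis convention is fixed package-wide:
slice axis = longitudinal y, row axis = vertical z, column axis = lateral
x; distances come from `PixelSpacing` and `SliceThickness`.

Marker detection binarizes at 800 HU (the markers are > 1000 HU; 800
leaves partial-volume margin), labels 2D 8-connected components per slice,
gates them at 2–200 px to reject speckle and non-marker structure, and
clusters components across slices into physical markers. Centroids are
unweighted pixel-centre means. The phantom centre is the body-mask
centroid on the middle slice, and all ROI geometry is expressed relative
to it, which makes the analysis robust to the phantom not being exactly at
isocentre. Both phantom versions are handled by the three-marker rule:
when four markers qualify, the three with maximal pairwise-distance sum
are kept (ties: larger area, then scan order). Edges are labelled
A–B < B–C < C–A by ascending length, so labelling is invariant under
phantom rotation; vertex B is the endpoint shared by the two shortest
edges.

The middle slice is the rounded (half-up) area-weighted mean slice of the
marker voxels; the unrounded value is kept and used for the longitudinal
distance, which is measured from the fractional marker plane to the outer
edge of the outermost slice whose body-mask area is at least 50% of the
maximum cross-section, on the nearest end contained in the scan. With this
convention a centred 180 mm phantom yields exactly 90.0 mm.

The uniform slice lies 10 mm from the middle *away* from the plugs, the
contrast slice 50 mm *toward* them. The plug side cannot be told from the
±10 mm slices themselves (the plugs start ~30 mm out), so both selections
share one side detector: the body-mask sigma of the two candidate slices
at the ±50 mm contrast distance — plugs of different densities inflate the
cross-sectional sigma on their side. Both directions can be forced in the
configuration.

ROI membership is pixel-centre-in-circle with an inclusive boundary, and
sigma uses the n−1 denominator; both facts matter when comparing against
an independent implementation and are frozen package-wide. Baseline
matching for the contrast test pairs measured and baseline HU lists by
rank, which attains the minimum total |difference| one-to-one assignment
on a line (verified in the tests against exhaustive enumeration of all 7!
pairings); this makes the comparison independent of which hole a plug
occupies. All tolerance comparisons are inclusive — a deviation of exactly
1.0 mm passes the SRS test — matching how a boundary-value QA is read in
practice.

The resolution plug is found as the global maximum of the HU sigma in a
14 mm search ROI over all 20 hole positions on the candidate slices ±35
and ±90 mm from the middle (insertion depth and direction). Candidate
slices are truncated *toward* the middle rather than rounded, because the
±90 mm position touches the phantom end surface and its hole pattern
extends inward; plain rounding can land half a slice into air. If the
runner-up sigma is within 10% of the maximum the search refuses to guess
and raises a recoverable error; a manual hole/offset override bypasses it.
The display window is the 1st–99th percentile of the cropped sub-image
(a constant crop windows to the value ± 1 HU).

A QA run aggregates to `pass` only if every graded test passed *and* the
inspector graded resolution pass; any graded failure (or a failed visual
grade) gives `fail`; anything ungraded or errored gives `incomplete`.
Uniformity and noise are never graded against baseline — they are
properties of the image itself; baseline values are printed for reference
only. The canonical output is a deterministic JSON sidecar (no wall-clock
fields; numerics serialized with 17 significant digits so they round-trip
bit-exactly); the one-page PDF with marker/ROI/resolution panels is a
rendering of it.

## The synthetic phantom

Scanner data cannot ship with the package, so every test runs on a
simulated phantom with exact ground truth. The generator renders the
cylinder (body 0 HU in −1024 HU air), markers (1100 HU, 6 mm diameter,
3 mm long) in the mid-plane, density plugs in 25 mm holes on two rings
(12 at r = 115 mm, 8 at r = 65 mm — the hole count is the phantom's; the
exact ring geometry is a documented package constant, since the
commercial drawing is not published), and a resolution plug modelled as a
±300 HU uniform per-voxel jitter plus drilled air-hole groups of
0.8–2.0 mm. A voxel takes a structure's HU if its centre is inside the
structure (no antialiasing — ground truth stays analytic), Gaussian noise
of sigma 20 HU is added everywhere, and the result is quantized to integer
HU as any CT reconstruction would.

The defaults are the routine QA conditions: fine-mode 1 mm slices,
0.762 mm pixels, a scan margin of air at both ends (220 slices), three
markers whose pairwise distances are set to a machine-acceptance baseline
of 101.0 / 147.7 / 226.4 mm (the absolute angular placement is not
published; the triangle is centred on the axis), the seven vendor density
plugs at their reference mega-voltage HU values (LN-300 −685.7 … cortical
bone 668.3), one hole open to air, and the resolution plug at +35 mm.
Noise sigma 20 HU reflects a well-behaved machine (the acceptance-era
baseline in routine QA records runs ~16–19 HU). In-plane rotations of
0/90/180/270°, per-axis geometric scale errors, marker-plane shifts and
either insertion position of the resolution plug are all injectable, with
the ground truth transformed analytically.

What the simulation does *not* model: beam-hardening cupping, ring and
streak artifacts, detector afterglow, partial-volume blur (no
antialiasing), or the true hole coordinates of the commercial phantom.
Passing tests therefore demonstrate the correctness of the measurement and
grading logic under known geometry and Gaussian noise — not robustness to
every scanner artifact. The ambiguity guard and the manual override exist
precisely because real artifacts can defeat the automatic plug search.

`write_series()` emits the simulated volume as a standard explicit-VR
little-endian DICOM series (one file per slice, `InstanceNumber` 1..n),
and `read_series()` reads it back bit-exactly; the test suite additionally
cross-checks the writer against an independent DICOM implementation. The
codec is deliberately minimal — uncompressed single-frame CT only.

## Numerical choices

* Slice-index rounding is half-up (`floor(x + 0.5)`), so the middle slice
  does not depend on the parity of the slice count.
* Inclusive comparisons use an epsilon of 1e-9 to keep boundary cases
  (exactly 1.0 mm, exactly 30 HU) stable against floating-point noise.
* Marker clustering across slices uses a 15 mm radius — far below the
  > 100 mm marker separations, far above one marker's footprint.
* The degenerate-marker guard rejects centroid pairs closer than 1 mm.
* The sigma-search ambiguity margin is 10%: at the default pixel size the
  search ROI holds ~260 pixels, so sigma estimates scatter ~4%, and a
  textureless volume (every candidate just noise) reliably trips the
  guard. At very coarse grids (2 mm pixels, ~38 px ROIs) the scatter grows
  to ~11% and a homogeneous volume may occasionally produce a >10% gap by
  chance — another reason the guard is a recoverable error, not a silent
  pass.

## Validation sizes

The test-suite and acceptance-script sweeps run the generator at reduced
sampling so hundreds of phantom realizations stay cheap, with tolerances
that scale with the grid: geometric recovery runs at 2 mm pixels / 280 mm
FOV over 20 seeds × 4 rotations × {1, 2} mm slices against the bound
max(pixel, slice)/2 + 0.1 mm (measured worst case ~0.43 mm vs the 1.1 mm
bound); resolution localization runs the full 320-case seed x insert x rotation cross at 2 mm / 2 mm; pixel-count
sensitive checks (big-ROI sigma at n > 4000 px, contrast recovery within
3σ/√n) use the full 0.762 mm default; the end-to-end DICOM round-trip uses
1.5 mm pixels and a 200-slice series. These sizes are the package's
validation choices and are stated here so they can be reproduced exactly.

## Limitations

* HU-to-density calibration curves, dose recalculation, and artifact
  classification are out of scope; so are the non-imaging TG-148 items.
* The DICOM reader supports uncompressed implicit/explicit VR little
  endian, single-frame, as exported by the treatment consoles; compressed
  transfer syntaxes and multi-frame objects are rejected with a clear
  error.
* No MTF or automated visibility scoring: the resolution criterion stays
  with the inspector by design.
* The per-plug 30/50 HU split at |baseline| = 100 HU is a documented
  default; clinics that grade individual materials differently should set
  per-plug overrides, which the report then shows.
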