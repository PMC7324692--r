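# mvctqa

Automated monthly image quality assurance for mega-voltage CT (MVCT) scans
of the cylindrical "cheese" phantom used on helical tomotherapy platforms
(TomoTherapy, Radixact).

Daily image-guided setup on these machines relies on MVCT, so TG-148
prescribes a monthly image QA on the vendor phantom — but not a
measurement procedure, which leaves manual, analyst-dependent readings.
`mvctqa` is for the medical physicist running that QA: it reads the
exported DICOM series, measures everything measurable, grades it against a
persisted baseline, and emits a one-page PDF report with a machine-readable
JSON sidecar.

## What it computes

Writing the three fiducial marker centroids as $\mathbf{p}_A, \mathbf{p}_B,
\mathbf{p}_C$ (mm, from 8-connected component centroids in the binarized
mid-plane image), the geometric test grades

$$\max_k \left| d_k - d_k^{\mathrm{base}} \right| \le \tau, \qquad
d \in \{ \|\mathbf{p}_A-\mathbf{p}_B\|, \|\mathbf{p}_B-\mathbf{p}_C\|,
\|\mathbf{p}_C-\mathbf{p}_A\|, d_{BD} \},$$

with $\tau$ = 1 mm (SRS/SBRT) or 2 mm, where $d_{BD}$ is the longitudinal
marker-plane-to-surface distance. Uniformity grades
$\max_j |\bar{H}_{\mathrm{periph},j} - \bar{H}_{\mathrm{centre}}| \le 25$ HU
(dose-calculation use) over four cardinal 10 mm ROIs; noise reports
$\sigma_{CT}$ of the centre ROIs (informational); contrast pairs each
plug's mean HU with the nearest baseline HU (a rank pairing, which
minimizes the total absolute difference over all one-to-one assignments)
and grades $|\Delta \mathrm{HU}| \le 30$ (water-like) or $50$; the
spatial-resolution plug is auto-located as the global maximum of ROI
$\sigma$ over all 20 hole positions at the four candidate insertion
offsets (±35/±90 mm), windowed, and graded visually by the inspector.

A synthetic phantom generator with exact ground truth (geometry, plug HU
values, noise level all injectable) plus a DICOM series writer stand in
for scanner data everywhere, so the full pipeline is testable offline.

## Worked example

Simulate a phantom, establish a baseline, then analyze a copy with a 2%
geometric scaling error injected, in SRS mode:

```r
library(mvctqa)

g  <- generate_phantom(phantom_spec(pixel_spacing_mm = 1.5, fov_mm = 300, seed = 11))
r0 <- run_qa(g$volume)                       # no baseline: establishes one
save_baseline(r0, "baseline.json")

bad <- inject_distortion(g$volume, c(1.02, 1.02))
r2  <- run_qa(bad, baseline = "baseline.json",
              config = qa_config(mode = "srs"), resolution_grade = "pass")
r2
#> <qa_report>  overall: FAIL
#>   geometric (srs, tol 1 mm): fail
#>   label measured_mm baseline_mm deviation_mm
#> 1 A-B          102.        101.         1.46
#> 2 B-C          151.        148.         2.72
#> 3 C-A          230.        226.         3.72
#> 4 B-D           90          90          0
#>   uniformity: max |diff| 5.38 HU (tol 25) -> pass
#>   noise: sigma 19.78 HU (small ROI), 19.32 HU (big ROI) [informational]
#>   contrast: pass
#>   resolution plug: offset +35 mm, hole 9 (sigma 381.5 HU); visual grade: pass
```

The 2% scaling stretches the 101.0/147.7/226.4 mm marker distances by
1.5–3.7 mm — past the 1 mm SRS tolerance — so the geometric item and the
overall QA fail, while the image-quality items (untouched by a geometric
error) still pass. `tidy(r2)` gives the same content as a long tibble,
`glance(r2)` as a one-row summary, and

```r
render_report(r2, "qa_out", volume = bad)
```

writes the one-page `qa_report.pdf`, the canonical `qa_report.json`
sidecar and the windowed resolution-plug PNG. The same pipeline is
scriptable from a shell via `exec/mvctqa` (`simulate`, `baseline`, `run`
subcommands).

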