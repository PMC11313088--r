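# octcov

Automated quantification of stent strut tissue coverage in intravascular
optical coherence tomography (OCT).

## The problem

After coronary stent implantation, neointimal tissue gradually covers the
metallic struts; incomplete coverage is the imaging hallmark of delayed
healing and a risk factor for stent thrombosis, and it informs how long dual
antiplatelet therapy must continue. OCT resolves individual struts and
micrometre-scale tissue layers, but manual per-frame analysis is so laborious
that complete pullbacks are rarely read. `octcov` automates the analysis for
researchers working with stented OCT cross-sections: it reads multi-frame
DICOM pullbacks (or directories of single-frame images), and for every frame

1. removes vendor text/marker overlays with a color-pixel mask,
2. resamples the frame into polar (A-line x depth) coordinates,
3. segments the lumen by binarization refined with a cyclic radial active
   contour ("snake") and morphological cleanup,
4. detects metallic struts from strut-shadow components and per-A-line
   intensity-profile criteria (a bright bloom followed by a clear drop into
   its shadow), localizing each at the midpoint of its anterior edge,
5. measures the neointimal thickness over each strut (radial distance from
   the lumen contour to the strut's anterior edge) and labels the strut
   **covered** or **uncovered** — uncovered meaning tissue on neither side
   or on one side only,
6. fits a stent contour through the struts and reports lumen and stent area
   (stent area is reported as missing, with a reason, when visible struts
   span less than half the circumference).

A validation layer computes the usual agreement statistics — PPV/TPR of
strut detection under a distance-tolerance matching, Bland–Altman limits of
agreement for areas, Mann–Whitney comparison of thickness distributions —
against either manual annotations or the exact ground truth of the built-in
phantom generator. The phantom module renders synthetic OCT frames (Fourier
lumen, attenuating wall, strut blooms with trailing shadows, multiplicative
gamma speckle, optional guidewire shadow and overlay marks) so the whole
pipeline is testable without clinical data.

Key quantities, in the field's notation: detection is scored as
PPV = TP/(TP+FP) and TPR = TP/(TP+FN); agreement as mean difference
± 1.96·SD (limits of agreement); per-strut coverage as neointimal thickness
in µm and a covered/uncovered label.

## Worked example

Generate a five-frame synthetic pullback with known ground truth, analyze
it, and validate the detections against the truth:

```r
library(octcov)

suite  <- generate_suite(5, "speckle", seed = 7)
report <- analyze_pullback(lapply(suite$phantoms, `[[`, "frame"))
print(report)
#> <oct_report> 5 frames (5 analyzed, 0 failed)
#>   struts: 39 total, 31 covered, 8 uncovered (20.5% uncovered)

truth <- do.call(rbind, lapply(seq_along(suite$phantoms), function(i) {
  tr <- suite$phantoms[[i]]$truth$struts
  cbind(frame_index = i - 1L, tr[c("x_px", "y_px", "label", "thickness_um")])
}))
v <- validate_against_reference(report, truth)
print(v$all)
#> <oct_match> tp 37, fp 2, fn 0 | PPV 0.949, TPR 1.000
```

The report says all five frames were analyzable and 39 struts were found,
of which 8 lack tissue coverage on at least one side. The validation
matches detections to true strut positions within 150 µm: every generated
strut was recovered (TPR 1.0) and two detections did not pair with a true
strut within tolerance (PPV 0.949) — speckle occasionally splits or
displaces a shadow. Per-strut rows (angle, thickness in µm, label) and
per-frame areas are in `report$frames`; `analyze_pullback(..., out_dir =)`
writes them as CSV/JSON together with the resolved configuration.

A command-line front end with `analyze`, `phantom`, `validate` and
`version` subcommands is installed at `inst/cli/octcov.R`.

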