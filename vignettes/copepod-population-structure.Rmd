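---
title: "From plankton scans to copepod population structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plankton scans to copepod population structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zooscanr)
```

## The problem

Stratified day/night net tows through the upper 1,000 m of the subarctic
Pacific, scanned on a flatbed plankton imager, yield one record per captured
individual: a silhouette area in pixels plus a manual taxonomic annotation.
From that raw material this package reconstructs the population biology of
two large calanoid copepods with contrasting life histories: *Metridia
pacifica*, a diel vertical migrant (DVM) that ascends to the surface layer
every night, and *Eucalanus bungii*, a seasonal vertical migrant (SVM) that
spends its dormant months at depth with no day/night difference and shifts
its residence depth across the year.

The pipeline has four stages, each usable on its own:

1. **imaging** — segment a grayscale scan into objects and convert pixel
   areas into physical size;
2. **population** — turn per-object detections plus tow metadata into
   depth-stratified abundance/biovolume profiles and migration metrics;
3. **size structure** — ESD histograms, size-by-depth matrices, copepodite
   stage assignment, and the 2-mm *Metridia* species split;
4. **synthetic data** — a generator that emulates the sampling design so
   every stage is testable without field data.

## Measurement model

The imager digitises at a fixed pitch, 10.58 µm per pixel by default, so a
silhouette of $A_{px}$ pixels has area

$$A\,(\mathrm{mm}^2) = A_{px} \cdot (0.01058)^2 .$$

Size is summarised as the **equivalent spherical diameter** (ESD), the
diameter of the circle with the same area as the silhouette,

$$\mathrm{ESD}\,(\mathrm{mm}) = 2\sqrt{A/\pi},$$

and individual **biovolume** as the volume of the ESD-diameter sphere,

$$V\,(\mathrm{mm}^3) = \tfrac{4}{3}\pi\,(\mathrm{ESD}/2)^3 .$$

These are deliberate simplifications — a copepod is not a sphere — but they
are the standard currency of imaging-based plankton studies and are applied
identically to every individual, so ratios and distributions remain
meaningful. `area_px_to_mm2()`, `esd_from_area()` and `biovolume_from_esd()`
implement them with exact round-trip and monotonicity properties covered by
tests.

### Segmentation choices

Instrument-side processing is proprietary, so the in-package segmenter makes
its conventions explicit:

* objects are **dark on a light background**; with a background scan, the
  difference `background − image` is thresholded, which cancels illumination
  structure;
* the default threshold is **Otsu's method**, with a numeric override.
  Because Otsu always produces a split, a class-separation guard (between-
  class mean separation must exceed 4× the within-class standard deviation)
  declares featureless images object-free instead of binarising noise;
* connected components use **8-connectivity**; labels follow the raster-scan
  order of each component's first pixel;
* an object's `area_px` is its **foreground pixel count** — the stand-in
  definition for the instrument's per-object area measure, whose treatment
  of interior holes is not documented;
* components under `min_area_px = 30` px (≈ 0.34 mm ESD, just below a
  335-µm net mesh) are dropped as specks; the cut is configurable;
* border-touching objects are kept and flagged, since no exclusion rule is
  part of the measurement convention;
* pixel coordinates are 0-based, bounding boxes half-open.

## Population arithmetic

Each net-layer sample carries its depth bounds, the seawater volume the net
filtered (flowmeter), and the **aliquot fraction** — the subsampled portion
of the sample actually scanned, between 1/2 and 1/128. For a layer count
$n$,

$$C = \frac{n / f_{\text{aliquot}}}{V_{\text{filtered}}}\ (\text{ind. m}^{-3}),
\qquad
A = C \cdot (z_{\text{bottom}} - z_{\text{top}})\ (\text{ind. m}^{-2}),$$

and the water-column total is the sum of the areal values over the eight
standard layers (0–50, 50–100, 100–150, 150–200, 200–300, 300–500, 500–750,
750–1,000 m). The vertical distribution is each layer's share of that total.
"Towing depth" is read as the layer **thickness**: it is the only reading
under which m⁻³ × m = m⁻² integration is dimensionally correct. Biovolume
profiles run the identical arithmetic on summed per-object sphere volumes.

Layers never towed are treated as missing, not zero, and by default a
profile demands contiguous 0–1,000 m coverage (`allow_partial = TRUE`
relaxes this). Day/night flags come from the tow metadata; the package never
recomputes them from sun angles.

The single-number summary of a profile is the **weighted mean depth**
(WMD), the areal-abundance-weighted mean of layer midpoints. Its resolution
is limited by the layer scheme — all mass in a layer sits at the midpoint —
which is why the no-migration tolerance used in the tests is one inter-layer
midpoint spacing. The **DVM amplitude** is WMD(day) − WMD(night): large and
positive for a nocturnal ascender, near zero for a seasonal migrant.

## Size structure and stage assignment

Histograms use half-open bins $[kw, (k+1)w)$ aligned to the origin with
$w = 0.1$ mm, weighted by each individual's areal-abundance contribution (or
1 for raw counts); binning conserves total mass exactly. The size-by-depth
matrix divides each bin's areal abundance across layers and normalises by
the column total, so the grand total is 100%.

Stage assignment replaces microscope staging with a transparent Gaussian
rule: each stage of the species contributes a Normal likelihood at the
observed ESD, built from the packaged per-stage reference (mean ± sd of ESD
for C1–C6F/M of both species, measured on stage-sorted individuals); with
equal priors the normalised likelihoods are posteriors and the argmax is the
call. Where stages genuinely overlap in size — *E. bungii* C4F/C4M, and
C5F/C5M against the small adult males (C6M) — no ESD rule can be accurate,
so the classifier **surfaces ambiguity** (flag raised when the top posterior
is under 3× the runner-up; threshold configurable) instead of hiding it. On
a simulated October population the flagged fraction for those late stages is
essentially 100%, which is the honest answer.

The *Metridia* assemblage is split at 2 mm ESD: *M. pacifica* below, the
three large congeners (*M. okhotensis*, *M. asymmetrica*, *M. curticauda*)
at or above. The boundary itself goes to the large group — an arbitrary but
documented convention, configurable via `threshold_mm`. ESD cannot resolve
the three large species from one another, so they stay one group. From the
packaged reference, adult females of *E. bungii* are 2.22× the ESD of
*M. pacifica* and therefore 10.9× (= 2.22³) the biovolume — the size
disparity that underlies their different migration strategies.

## What the generator emulates — and what it does not

`generate_population()` draws, per day/night condition, `n_individuals`
with: a copepodite stage from the scenario's stage weights; an ESD from the
stage's Normal(mean, sd) truncated at zero by resampling (the reference
reports only mean ± sd, so normality is an assumption); and a depth layer
from the stage-resolvable day or night probability vector. Physical
aliquot splitting is emulated by **binomial thinning** — each individual
survives into the scanned aliquot with its layer's aliquot fraction as
probability — matching the randomness of Folsom-style splitting rather than
deterministic division. Everything is reproducible under a fixed seed.

The four presets encode the qualitative patterns the analysis must resolve
as explicit per-layer probability vectors, so tests compare pipeline output
against the preset's own ground truth:

* `mpacifica_dvm` — deep day modes, a 0.6-probability 0–50 m night mode,
  adult males resident deep day and night;
* `ebungii_svm_october` — identical day/night vectors with 85% of mass at
  200–500 m, stages C3–C6F;
* `ebungii_july_recruitment` — young-heavy composition with C1–C4
  concentrated at 0–50 m day and night;
* `metridia_mixture` — the *M. pacifica* cohorts plus a >2 mm congener
  component. The congener ESD parameters (mean 2.9 mm, sd 0.25) are
  **synthetic**: no per-stage table exists for the large congeners, only
  adult-female measurements shown graphically.

Defaults that are field-anchored: the eight-layer scheme, the 1/2–1/128
aliquot range, mesh 335 µm and mouth area 1.5 m², the per-stage ESD table,
and the tow dates and day/night flags in the packaged metadata fixture.
Defaults that are this package's own choices, made once: per-layer filtered
volumes (6 m³ per metre of layer thickness, a plausible oblique-tow figure —
the field volumes were never published), the preset probability vectors and
stage weights, and the per-layer aliquot assignments (richer shallow samples
split harder).

What the generator does **not** emulate: real silhouettes (no shape, no
appendages, no preservation artefacts), taxonomic misannotation, net
avoidance or clogging, patchiness beyond multinomial sampling, and
inter-annual variability. Passing tests therefore demonstrate that the
arithmetic, conventions and estimators are correct and well calibrated under
the stated sampling model — not that field data would be this clean.

`generate_scan_image()` covers the imaging stage separately: non-overlapping
dark ellipses with exact rasterised pixel areas as ground truth, plus
Gaussian noise. Segmentation recovers counts exactly and areas to well
under 2% for semi-axes ≥ 10 px.

## Numerical and testing choices

* Fraction/percentage conservation is asserted to 1e−9 (profiles) and 1e−6
  (matrices); areal = concentration × thickness to machine precision.
* TSV output writes doubles at 6 significant digits so write–read–write
  cycles are byte-identical; aliquot fractions parse from `1/128`-style
  ratios or decimals.
* Stochastic tests fix their seeds and use bands derived a priori from the
  sampling model: binomial 95% bands with aliquot-thinned effective counts
  for layer fractions; 2-standard-error bands for recovered stage means. A
  2 SE band is a 95% interval, so multi-stage sweeps assert calibration
  (the expected number of in-band stages) rather than demanding every draw
  land inside — a guaranteed-all-inside test at 2 SE would be testing the
  wrong thing.
* Simulation sizes in the tests (300–2,000 individuals per condition,
  20 images of ≤ 6 objects, 1,000-draw reference cohorts) were chosen as
  the smallest sizes at which the statistical bands above are meaningfully
  tight; the full suite runs in seconds.
* Degenerate inputs are contracts, not crashes: empty populations yield
  valid metadata and zero-total histograms; featureless images yield empty
  detection sets; zero-thickness layers, overlapping schemes, orphan sample
  ids, non-positive volumes and aliquots outside (0, 1] are rejected with
  specific errors.

## Known limitations

* ESD-based staging is honest about, but cannot fix, late-stage overlap in
  *E. bungii*; sex ratios for C4–C5 and C6M abundance are unreliable from
  size alone.
* WMD inherits the layer scheme's coarseness; migration amplitudes below
  ~50 m (the narrowest midpoint spacing) are not resolvable.
* The spherical biovolume model understates shape variation between taxa;
  cross-taxon biovolume comparisons carry that bias.
* The 2-mm split misassigns any unusually large *M. pacifica* female or
  small congener; it is a population-level, not individual-level, rule.
* Synthetic filtered volumes scale with layer thickness; absolute areal
  abundances from the fixture are therefore internally consistent but not
  field-calibrated.
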