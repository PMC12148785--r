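---
title: "Evaluating breast radiotherapy plans with planqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating breast radiotherapy plans with planqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planqc)
```

## The problem

External-beam breast treatment (EBBT) planning is high-volume work under
several competing fractionation protocols, each with its own dose
constraints for the planning target volume (PTV) and organs at risk
(OARs). Two distinct questions arise at plan review time:

1. *Does the plan satisfy its protocol?* — a mechanical check of DVH
   metrics against published limits, worth automating because it is done
   dozens of times a day and limits differ per protocol.
2. *Is the plan as good as it should be here?* — protocol limits are
   generic and technique-agnostic; a plan can pass every constraint and
   still be mediocre for a given centre, patient geometry, and technique.
   Comparing against the centre's own accumulated plans answers this
   without any trained model: the library *is* the model.

`planqc` implements both: a constraint engine with traffic lights and a
fulfilment score, and a community plan library with similarity filtering
and a per-metric percentile score.

## The evaluation pipeline

A plan enters as a DICOM-RT triplet (dose grid, structure set, beam/plan
description) or as a cumulative-DVH table. The pipeline is:

1. **Property detection.** Laterality from side tokens in target names
   (both sides present means bilateral; no token means the caller must
   override — guessing would silently flip ipsi/contra organs). Technique
   from the beam mix: static open fields → 3DCRT, dynamic-MLC static
   gantry → IMRT, arcs → VMAT, static plus modulated → HYBRID.
2. **Structure matching.** Case-insensitive token matching against an
   editable lexicon (English + Italian tokens shipped). The lexicon is
   configuration, not code: structure naming is the least standardized
   thing in any clinic. Ties break by longest matched token, then
   alphabetically; identically named candidates are a hard error.
   Unmatched roles are simply NOT_EVALUATED — reporting an un-checked
   constraint as passed or failed would both be wrong.
3. **Protocol selection** from (dose per fraction, fraction count, PTV
   count) against each protocol's schedule windows. Windows are disjoint
   by construction so selection is deterministic; one shipped protocol
   (the 40.05 Gy / 15 fx whole-breast arm of the elderly PBI trial) has
   no auto-selection window because its schedule is indistinguishable
   from the moderate-hypofractionation protocol — it is applied only by
   explicit override, and the protocol file says so.
4. **DVH + constraints.** Each constraint's metric is computed on the
   mapped structure's cumulative DVH and compared inclusively at
   1-decimal display precision (a value the report prints as "20.0"
   must not fail a "≤ 20" limit).

## DVH computation

The dose grid is axial, uniform, voxel-centred (anything else is rejected
loudly). Structure contours are closed planar polygons; each is assigned
to the nearest grid plane within half a slice thickness and membership is
decided by the even-odd rule, so an inner contour subtracts (the standard
hole convention). Each contour plane contributes a slab one slice thick —
the usual planar-contour volume model. In-plane, voxels are subdivided
`supersample` times per axis (default 2) and classified at sub-centres;
this converges to the exact fractional overlap for the synthetic box
fixtures and is the knob to turn for small structures.

The cumulative curve is built on fixed-width bins (default 0.05 Gy, well
below any shipped constraint threshold). The value at a bin edge is the
volume receiving at least that dose; bin assignment snaps doses lying on
an edge (to within float noise) upward, so `V26Gy` of a uniform 26 Gy
region is exactly 100 %. Consequences of binning, documented rather than
hidden: `Dmean`/`Dmax`/`Dmin` carry a half-bin (0.025 Gy) bin-centre
convention; inverse lookups (`D2%`) interpolate linearly and resolve flat
ties to the lowest dose achieving the volume; `D0%` returns Dmax and
`D100%` returns Dmin so the operator is total. Metrics in cm³ require the
curve to carry an absolute volume; imported `%`-only tables fail those
metrics with a unit error instead of inventing a volume.

Metric names use a small grammar that appears verbatim in protocol files,
library column headers and reports: `V<dose>Gy[%|cc]`, `D<vol>%[Gy]`,
`D<vol>cc[Gy]`, `Dmean[Gy]`, `Dmax[Gy]`, `Dmin[Gy]`.

## Scores

**Fulfilment score.** Percent of *evaluated* PTV + Main-OAR constraints
(standard and extra alike) whose status is GREEN or YELLOW, rounded to the
nearest integer. YELLOW counts as fulfilled deliberately: yellow means the
mandatory limit was met and only the stricter optimal missed, and the
score measures fulfilment of the protocol, not perfection. Other-OAR
constraints are informational and excluded. This is a design choice the
user should know when comparing scores across centres.

**Community score.** For one metric, `floor(100 × #strictly-worse / n)`
over the similarity-filtered library. Strictly-worse (not ≥) makes ties
count against the plan under review — a conservative reading —, and
flooring makes 3 worse plans out of 24 print as 12, not 13. The similarity
filter conjoins protocol, laterality, technique, target composition and
modifier constraints (e.g. excluding breath-hold plans when the plan under
review is free-breathing); every field except protocol is optional,
because hard-coding which properties "matter" would bake one centre's
caseload into the tool. An overall cross-metric community score is out of
scope by design; per-metric scores stay interpretable.

**Inspector statistics.** min/max/mean/SD plus a histogram with
`ceil(sqrt(n))` bins clamped to 5–20, and flags for the query value lying
beyond the community mean and mean + 1 SD in the metric's worse
direction. The MU-Sum check reuses this machinery with
greater-is-worse, since total monitor units proxy modulation complexity.

## Change detection

A library column in export order forms a chronological series; splitting
it at an intervention gives BEFORE/AFTER groups. Two one-tailed
Mann-Whitney-Wilcoxon U tests are run: on raw values (did the metric
improve?) and on per-group squared deviations
`Q.DEV(x) = (f(x) − ⟨f⟩)²` with the "dispersion shrank" alternative.
`⟨f⟩` defaults to each group's own mean (`PER_GROUP`): comparing
deviations from a common grand mean would confound a location shift with
a dispersion change, which is exactly what the two separate tests are
meant to distinguish; `WHOLE` is available for the reader who wants the
other convention. The caller must pick the raw-value alternative
explicitly (lower-is-better for ≤-constrained metrics) — the package
refuses to guess the direction of "improvement".

P-values: exact null enumeration (via the Wilcoxon distribution) when
n₁ + n₂ ≤ 12 and no ties are present; otherwise the normal approximation
with midrank tie correction and a 0.5 continuity correction. The suite
verifies the exact branch against brute-force enumeration of all
labelings and calibrates the approximate branch by simulation (type-I
rate at α = 0.05 within Monte-Carlo error over 1000 null replicates).

## The synthetic world, and what a green test establishes

All fixtures are generated: no clinical data exists in or enters the
repository.

*Phantoms* are axis-aligned boxes — dose regions snapped to voxel
boundaries and rounded to the 0.05 Gy bin, structures free to sit at
fractional in-plane positions. This is deliberate: box geometry makes
every DVH metric analytically exact (1-D overlap products), so the
companion table written next to each phantom is a true oracle, not a
regression snapshot. The demo phantom mirrors a right-breast 26 Gy / 5 fx
case: PTV inside the prescription region, a 3 Gy ipsilateral-lung bath, a
1 Gy heart bath, zero-dose contralateral structures, two ~200 MU arcs at
600 MU/min (MU sum 396.3) plus a setup field. The generator is fully
deterministic (derived DICOM UIDs, no RNG), so fixture files are
byte-identical across runs.

*Libraries* are seeded draws: categorical mixes for
laterality/technique/targets/users, per-metric normal, lognormal or
uniform distributions (defaults chosen where a well-optimized clinic
sits: ipsilateral-lung V16 ≈ 13 ± 3 %, heart mean ≈ 1.5 ± 0.4 Gy,
MU sums ≈ 400 ± 60), or explicit value vectors for exact-count harnesses.

What green tests do **not** establish: accuracy on real anatomy (no
curved contours, no inhomogeneous dose gradients inside a structure slab),
robustness to the DICOM dialects of arbitrary vendors (the codec reads
the Explicit-VR-Little-Endian, defined-length subset it writes), or the
clinical appropriateness of the shipped constraint tables — those are
editable text files with per-line source tags, and only a handful of
limits (contralateral-lung V3Gy ≤ 10 %, heart mean ≤ 2 Gy, ipsilateral
V16Gy ≤ 20 %) should be treated as fixed reference points.

## Numerical and design choices

- Bin width 0.05 Gy, supersample 2 by default: sub-constraint resolution
  at interactive cost; the oracle suite runs at 3.
- Inclusive comparisons after rounding to 1 decimal: matches how a
  clinician reads "≤ 20" against a report that prints one decimal, and is
  deterministic at boundaries.
- Monitor units are per-fraction metersets (standard DICOM semantics) and
  the MU sum is their algebraic sum over treatment beams; setup beams are
  excluded, and plan sums skip all beam-level sanity checks rather than
  failing them.
- Sanity thresholds (1 isocenter, MU sum in [50, 1500], dose rates
  {400, 600} MU/min, X-jaw ≤ 150 mm for modulated beams, setup couch
  within 0.5°) are site-configurable preferences; the X jaw is the checked
  dimension because tangential modulated breast fields rarely need wide X
  apertures.
- The library CSV is versioned (`#schema=1`), uses role-qualified metric
  headers (the same metric can constrain two roles), stores a salted-hash
  patient key rather than any identifier, and keeps duplicate exports of
  a plan (chronological series semantics); appending is lock-guarded.
- Empty comparable cohorts yield "no comparable plans" (n = 0), never an
  exception: an empty library is the normal state of a new installation.

## Known limitations

Axial grids only; nearest-plane slab model in z (no inter-plane
interpolation); no biological metrics (EQD2, gEUD); name-based structure
matching only (no geometric laterality heuristics); bilateral plans are
detected but evaluated against a single protocol; the community approach
compares discrete DVH values, not whole curves, and carries no spatial
information — it is a feedback mechanism, not a dose predictor.
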