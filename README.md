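# planqc

Automatic evaluation of external-beam breast radiotherapy (EBBT) plans:
DVH-based protocol constraint checking with traffic-light statuses, a
protocol fulfilment score, a community plan library with similarity
filtering and percentile scoring, a plan sanity check, and chronological
change-detection statistics. Vendor-independent: plans enter either as
DICOM-RT triplets (RTDOSE + RTSTRUCT + RTPLAN) or as tabular cumulative-DVH
exports, so the engine runs without any treatment planning system attached.

## Who it is for

Medical physicists and dosimetrists planning breast treatments under the
common hypofractionation protocols (26 Gy / 5 fx, 28.5 Gy / 5 weekly fx,
40 Gy / 15 fx moderate hypofractionation, 30 Gy / 5 fx partial breast).
Each protocol prescribes dose constraints of the form
`V_x Gy ≤ v %` (volume receiving at least x Gy), `D_v% ≤ d Gy` (dose to the
hottest v % of a structure), and mean/max dose ceilings, over the PTV and
the organs at risk (lungs, heart, left coronary, contralateral breast, …).
Checking them by hand is slow and error-prone, and protocol limits alone
say little about whether a plan is as good as it *could* be at your centre;
`planqc` automates the first problem and uses an accumulating plan library
to address the second.

## The scores

* **Traffic lights** — each constraint is GREEN (met, optimal if one is
  defined), YELLOW (mandatory met, optimal missed), or RED (mandatory
  violated); extra (non-trial) constraints are starred. Comparisons are
  inclusive at 1-decimal display precision.
* **Fulfilment score** — `100 × (# evaluated PTV + Main-OAR constraints
  with GREEN/YELLOW) / (# evaluated)`, rounded to the nearest integer.
  Unevaluated constraints (unmapped structures) are excluded from both
  sides.
* **Community score (per metric)** — `floor(100 × #worse / n)` where
  `#worse` counts similarity-filtered library plans whose value for that
  metric is *strictly* worse (greater for ≤-limits, smaller for coverage).
  100 means the plan beats every comparable community plan.
* **Change detection** — for a chronological metric series split at an
  intervention, a one-tailed Mann-Whitney-Wilcoxon U test on the raw
  values (location shift) and on the per-group squared deviations
  `Q.DEV(x) = (f(x) − ⟨f⟩)²` (dispersion reduction). Exact enumeration
  p-values for n₁+n₂ ≤ 12 without ties, normal approximation with tie and
  continuity corrections otherwise.

## Worked example

```r
library(planqc)
d   <- file.path(tempdir(), "demo")
lib <- file.path(tempdir(), "community.csv")
make_phantom(demo_phantom_spec("clean"), d)       # DICOM-RT triplet
make_library(n = 24, out_path = lib, seed = 1,
             laterality = c(RIGHT = 1), technique = c(VMAT = 1), bh_p = 0,
             metrics = demo_library_metrics())    # 24 comparable plans
planqc_cli(c("evaluate", "--dicom-dir", d, "--library", lib))
```

prints (exit status 0 because nothing is RED and the sanity check passed):

```
Protocol: FAST_FORWARD
Plan: RIGHT VMAT boost=FALSE nodes=FALSE
Plan sanity check: PASS (MU-Sum 396.3)

[PTV]
   PTV_BREAST V24.7Gy[%]               100.0  GREEN  >= 90 (opt 95)
   PTV_BREAST D2%[Gy]                   26.0  GREEN  <= 28.6 (opt 27.8)
[MAIN_OAR]
   LUNG_IPSI V8Gy[%]                     0.0  GREEN  <= 15
   HEART V1.5Gy[%]                       0.0  GREEN  <= 30
   HEART V7Gy[%]                         0.0  GREEN  <= 5
  *LUNG_IPSI V16Gy[%]                    0.0  GREEN  <= 20  CB=100%
  *LUNG_CONTRA V3Gy[%]                   0.0  GREEN  <= 10  CB=100%
  *HEART Dmean[Gy]                       1.0  GREEN  <= 2  CB=79%
  *BREAST_CONTRA Dmean[Gy]               0.0  GREEN  <= 1
[OTHER_OAR]
  *ESOPHAGUS Dmean[Gy]                     -  NOT_EVALUATED <= 3
  ...

SCORE: 100% of evaluated PTV + Main-OAR constraints met
```

Reading it: the protocol was auto-selected from 26 Gy in 5 fractions with
one PTV; the phantom's PTV sits entirely in the 26 Gy region so coverage is
100 %; the heart bath at 1 Gy keeps its mean below the 2 Gy extra ceiling
and beats 79 % of the 24 comparable community plans (`CB=79%`); the
other-OAR constraints are NOT_EVALUATED because the phantom has no
esophagus/stomach/liver/thyroid/skin structures, and they do not count
toward the score. The MU sum (396.3 = 200.1 + 196.2 over the two treatment
arcs) passed the sanity range.

Other subcommands: `inspect` (histogram + min/max/mean/SD + community
score for one metric), `sanity`, `cohort` (change detection on a library
column), `make-phantom`, `make-library`. `--format JSON` emits the full
report machine-readably; `--export` appends the plan to the library CSV.

## Layout

- `R/dicom.R` — minimal DICOM Explicit-VR-LE codec (read/write)
- `R/rtio.R` — RTDOSE/RTSTRUCT/RTPLAN + DVH-table readers, data model
- `R/dvhcore.R` — DVH computation, metric grammar (`V16Gy[%]`, `D2%[Gy]`, …)
- `R/planmodel.R` — laterality/technique detection, structure-role matching
- `R/protocols.R` — protocol tables (editable text files), traffic lights
- `R/scoring.R`, `R/planlib.R`, `R/sanity.R`, `R/cohortstats.R`
- `R/synthgen.R`, `R/presets.R` — synthetic phantoms and libraries
- `R/cli.R`, `inst/cli/planqc` — command-line surface
- `vignettes/plan-evaluation.Rmd` — the methods vignette
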