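---
title: "Cleaning semi-structured echocardiography exports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning semi-structured echocardiography exports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoclean)
```

## The problem

Echocardiography PACS databases hold rich clinical information, but much of
it sits in free-text report sections ("moderate aortic stenosis", "LV
function appears mildly and globally impaired") and in numeric fields with
inconsistent conventions (heart rate as a range, height sometimes in
centimetres, column names that differ across report versions). `echoclean`
turns such a semi-structured, multi-chunk delimited export into a single
clean, typed, de-identified table, and quantifies how faithfully the
automatic rules reproduce a gold standard.

The pipeline runs in a fixed order: load and stitch chunks; rename columns
through alias profiles; drop variables where every observation is missing;
pseudonymise; demographics (date, age, sex, height/weight/BMI); indication
flags; cardiac rhythm and heart rate; left-ventricular numerics; LV/LA free
text; mitral, aortic, pulmonary and tricuspid valves; RVSP; diastolic
function; right-ventricular free text; then export, dropping the raw text
columns and keeping the earliest study per patient. Every recode and
exclusion is written to an audit log so the cleaning is reviewable.

## Phrase rules as data

Free-text grading uses ordered, declarative phrase rules
(`rule_set()`, `classify()`), not hard-coded logic, so a laboratory can
re-tune the shipped phrase sets against its own reporting conventions — the
intended workflow is iterative: classify, inspect disagreements with
`validate_extraction()`, edit the rules (they round-trip through YAML via
`write_rule_sets()`), and validate again.

Rules come in two kinds. *Direct* rules are precise patterns — typically a
severity adjective adjacent to the lesion word ("moderate regurgitation",
"mild AS"). *Catch-all* rules only require co-occurrence of a severity
token and a lesion token within one sentence. All direct rules are
evaluated before any catch-all (enforced by the constructor), which is what
makes "mild regurgitation and moderate stenosis" grade the regurgitation
mild: the direct mild rule fires before the moderate catch-all ever sees
the sentence. Compound grades (mild-to-moderate, moderate-to-severe) are
ordered before the simple grades because the simple adjective is a
substring of the compound. Negations ("no stenosis", "trivial
regurgitation") are explicit rules evaluated before the positive severity
rules.

Aortic valve disease has its own layered order: replacement terms (AVR,
prosthesis, TAVI) first, so a replaced valve is coded AVR regardless of
the rest of the sentence; explicit severities next; any mention of
thickening or sclerosis after that (so "severe stenosis of a thickened
valve" grades severe, while thickening without a severity is sclerosis);
the default is none. Valve morphology defaults to tricuspid when the
structure is not stated — a bicuspid valve is a clinically significant
finding that would not go unreported — and very rare morphologies
(unicuspid, quadricuspid) mark the study excluded from morphology
analyses.

Design details a re-user should know:

* **Sentences** are delimited by `.`, `;` and newlines. Report sections
  are short clause lists, so this coarse split is adequate; the generator
  joins section templates with `". "` for the same reason.
* **Case** is ignored everywhere.
* **Redundant routes.** Several catch-alls accept alternative supporting
  tokens (e.g. chamber words for size grading, "systolic"/"function" for
  function grading). This redundancy is what keeps agreement high when
  individual words are corrupted; the severity word itself is deliberately
  irreplaceable. No fuzzy matching or spelling correction is attempted —
  misspellings observed in practice should be added as rule variants.
* **Intermediate grades** are levels of their own; collapse them
  afterwards if a four-grade analysis is wanted.

## Numeric rules

All numeric cleaning returns a value plus a provenance and a recode
reason, and every recode lands in the audit log.

* **Heart rate** (bpm): ranges "a–b" (hyphen, en-dash, em-dash or "to")
  are recoded to the mean of the endpoints ("120–180" becomes 150);
  values strictly above 200 bpm are excluded. The cut is strict (`> 200`)
  because the rule is phrased as "over 200".
* **BMI** (kg/m²): weight / height². Heights above 3 are treated as
  centimetres. Raw pairs with height in 20–250 and weight in 1.2–2.2 are
  taken as transposed, swapped back and flagged for review — an automated,
  logged version of what would otherwise be a handful of manual
  corrections. BMI at or above 70, or at or below 14, is recoded missing
  (closed bounds at both thresholds, as the rule is stated).
* **Physically positive fields** (wall thicknesses, diameters, velocities,
  gradients, VTIs, areas, E/A and E/e′ ratios, LAVi): a parseable value
  `<= 0` is impossible and becomes missing with reason `nonpositive`.
* **LVEF** (%): when several methods were recorded, the most trusted
  available one wins, in the order modified biplane, modified apical four
  chamber, modified apical two chamber, Teichholz 2D, M-mode cube, M-mode.
* **RVSP** (mmHg): the direct numeric field is used when present;
  otherwise the free text is scanned and the *last* number immediately
  preceding "mmHg" is taken (summary statements tend to close a section;
  multiplicity is not otherwise specified). Text-extracted values carry a
  review flag.
* Decimal commas are not parsed; the target exports use decimal points.

## Derived variables

* **Dimensionless index** = LVOT VTI / AoV VTI, missing if either input
  is.
* **Any mitral calcification** is true when annular calcification is
  present or mitral stenosis is graded above none.
* **Diastolic function** uses the two-arm guideline decision tree split at
  LVEF > 50%. In the normal-EF arm four criteria are counted (average
  E/e′ > 14; septal e′ < 7 cm/s or lateral e′ < 10 cm/s; TR Vmax >
  2.8 m/s; LAVi > 34 mL/m²): a majority positive is dysfunction, a
  majority negative normal, an exact split indeterminate, and fewer than
  two evaluable criteria not assessable. In the reduced-EF arm E/A ≤ 0.8
  with E ≤ 50 cm/s is grade I and E/A ≥ 2 is grade III; the intermediate
  band is resolved by the same majority count over the three remaining
  criteria, with ties indeterminate. A missing LVEF (or missing E/A in
  the reduced arm) is not assessable. All thresholds are configuration
  (`diastolic_criteria()`) with the defaults above; special-case pathways
  of the full guideline (AF, MAC-specific caveats) are out of scope.

## De-identification

Each unique patient identifier receives a random 10-character ID drawn
from uppercase letters and digits minus the visually ambiguous O/0 and
I/1 (transcription safety). The mapping is a bijection kept in a lookup
table that must be stored separately from the de-identified data — the
writer refuses to place both at the same path. Re-encountered patients
keep their prior ID, so incremental cleans are stable. Generation is
seeded for reproducibility; study dates are retained, and no claim of
formal k-anonymity is made.

## The synthetic generator

Because the clinical database cannot be shipped, `simulate_echo_export()`
produces exports with the same failure modes and a hidden ground truth,
making every stage testable end to end. It emulates: multi-chunk exports
whose chunks cycle through column-alias profiles (two shipped report
dialects, including different date formats); free-text sections built
from a per-variable phrase bank; heart rates written as ranges; height
recorded in centimetres; transposed height/weight pairs; extreme values
(heart rate above 200, weight implying BMI ≥ 70, non-positive
measurements); per-field missingness; repeat studies with strictly later
dates; and typos.

Defaults were chosen once as plausible laboratory conditions: typo rate
0.02 per token, numeric missingness 0.05 per field, transposition 0.002
(of the order of tens per tens of thousands of studies), range-formatted
heart rate 0.15, each extreme-value type 0.005, repeat studies 0.15,
centimetre heights 0.2, three chunks. Level prevalences approximate a
general echo-lab case mix (e.g. half of studies with no aortic valve
disease, sinus rhythm in 60%). Typos never touch tokens that appear in
any classification pattern (matched by stem), so recovery is determined
by rule coverage rather than luck; an `adversarial` switch inverts this
and corrupts exactly the keyword tokens, which is how robustness is
measured. Text-section missingness is left at zero in the shipped
conditions because a blanked section makes the recorded true level
unrecoverable by construction; missing text is exercised in unit tests
instead.

What the generator does **not** emulate: real narrative variability
beyond the phrase bank, inter-observer wording drift, contradictory
statements within a report, non-English text, and correlations between
pathologies (levels are sampled independently, except that a replaced
aortic valve suppresses the native-morphology sentence). A perfect
synthetic round trip therefore shows that the rules cover the shipped
phrase inventory exactly — not that they cover any particular hospital's
phrasing, which is what the iterate-and-revalidate workflow is for.

## Validation

`validate_extraction()` draws a seeded simple random sample (default 100
studies), compares each variable against the gold standard and reports
percent agreement and Cohen's kappa,

$$\kappa = \frac{p_o - p_e}{1 - p_e},$$

with chance agreement computed from the marginal label frequencies.
Pairs with a missing label on either side are dropped (a flag turns
missing into a category instead); when both sequences carry one identical
label, kappa is defined as 1. The kappa is unweighted by default —
grades are ordinal but an unweighted statistic is the stricter, more
common report — with linear and quadratic weights available. Indication
flags are compared per category and summarised by their mean kappa. The
implementation is tested against an independent brute-force
confusion-matrix oracle to 1e-12 and against `e1071::classAgreement`.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data:
round-trip checks on 400 studies, robustness under 5% adversarial keyword
corruption on 1,000 studies, kappa oracle equivalence on 1,000 random
paired sequences (lengths 2–500, 2–6 categories), de-identification
invariants on 10,000 patients, and determinism/dedupe checks on 300
studies with 30% repeats. These sizes give stable statistics while
keeping a full run in tens of seconds. Dedupe ties on identical dates are
broken by stable input order; rows with unparseable dates are excluded
with an audit entry; reruns on identical input are byte-identical.

## Limitations

The shipped phrase bank and rules are a starting inventory, not a
universal one; agreement on real exports depends on local conventions and
should be measured with the validation workflow before any analysis.
Statistical or neural text methods, spelling correction and non-English
reports are out of scope, as are DICOM/PACS connectivity and linkage to
administrative outcome data.
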