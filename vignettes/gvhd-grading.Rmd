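---
title: "Methods: the GvHD grading and course-classification rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the GvHD grading and course-classification rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvhdgrade)
```

This vignette is the package's own account of the rules it implements,
the places where the printed sources are ambiguous, and the choices made
there. The package is a rule engine, not a statistical model: its
correctness claims are exact reproduction of published thresholds, and
its tests are enumeration and boundary scans rather than estimation.

## Acute GvHD: organ staging

Acute GvHD involves exactly three target organs — skin, liver and the GI
tract — staged 0–4 (upper GI 0–1). The engine stages from raw findings:
rash and bullae extent in % body surface area (BSA), total serum
bilirubin, a symptom diary for the upper GI tract, and stool
volume/episode counts for the lower GI tract.

Numerical conventions where the printed bands leave gaps:

* **Bilirubin bands.** Staging is canonical in mg/dL with half-open
  bands [2, 3.1), [3.1, 6.1), [6.1, 15], (15, ∞): a value printed
  between bands (e.g. 3.05 mg/dL) falls to the lower stage. Inputs in
  μmol/L are divided by **17** before banding. The laboratory molar
  factor is 17.1, but every printed μmol/mg band pair embodies 17
  exactly (34/2, 51/3, 102/6, 255/15), and a rule engine owes fidelity
  to the printed thresholds: with 17.1 the stage-3/4 boundary would land
  at 256.5 μmol/L instead of the printed 255. The same constant is used
  when normalizing records, so staging is unit-invariant by
  construction.
* **Skin stage 4 (MAGIC).** The table prints bullae/desquamation
  ">5% of BSA" while the accompanying definition says "a minimum of 5%
  of the body surface area". The engine uses **≥ 5%** (the "minimum of
  5%" reading), together with generalized erythroderma, as the stage-4
  conjunction; the Glucksberg-family systems require erythroderma with
  any bullous formation. Rash-band boundaries read literally: 25–50%
  inclusive is stage 2, above 50% stage 3.
* **Lower GI (MAGIC).** Volume and episode criteria are disjunctive in
  the table, so when both are recorded the stage is the **maximum** of
  the two sub-stages. 1000–1500 mL/day is read inclusive (stage 2),
  above 1500 strict (stage 3). Children under 50 kg switch to the
  per-kg bands (<10 / 10–19.9 / 20–30 / >30 mL/kg/day; <4 / 4–6 / 7–10
  / >10 episodes/day); the pediatric volume path requires a recorded
  weight and errors otherwise. The 200 mL/episode (adult) and 3
  mL/kg/episode (child) conversion is exposed as
  `episodes_to_volume()` but never applied silently when both raw
  inputs exist. The volume-only Keystone/Glucksberg rows print strict
  bounds ("<500", ">500", ">1000", ">1500"); boundary values are
  assigned 500 → 1, 1000 → 1, 1500 → 2.
* **Upper GI.** "Persistent" symptoms mean anorexia with weight loss,
  nausea for ≥3 consecutive days, or ≥2 vomiting episodes/day for ≥2
  days. The Keystone column additionally requires histologic evidence
  (`upper_gi_biopsy_positive` is tri-state; unknown does not qualify),
  and its undefined "persistent nausea" duration borrows the MAGIC
  thresholds — a borrowed definition, visible in the staging contract.
  The original Glucksberg system does not stage the upper GI tract.

## Overall acute grade

Each system's overall-grade table is applied literally and shipped,
row by row, as `inst/rules/acute_overall.yaml`; the engine emits the
fired row ids as `rule_trace`. Two readings deserve note. The IBMTR
column's GI rows are taken as lower-GI only (it prints no upper-GI
grade trigger). The original Glucksberg system grades with performance
status: "mild"/"marked" decreases are mapped to Karnofsky bands
(mild <90, marked <70, grade IV <30), configurable and always flagged in
the trace as an extrapolation; because its printed rows leave gaps
(liver 1 alone with normal Karnofsky matches no row), any organ
involvement not matching a higher row is graded I via an explicit floor
rule, preserving "grade 0 exactly when all included organs are stage 0"
and monotonicity.

Organs whose manifestation is solely due to a non-GvHD cause are
excluded from the overall grade (equivalently staged 0, with the
exclusion and its reason always reported); concurrent mixed etiology is
graded fully, with no downgrade. Karnofsky never contributes outside
original Glucksberg.

On identical staging inputs MAGIC and Keystone agree on every one of the
250 stage tuples once grades III and IV are pooled; their exact
disagreements are confined to the III/IV split (stage-4 lower GI), and
differing upper-GI staging can move a patient only within grades 0–II.
The test suite asserts both exhaustively.

## Chronic GvHD: NIH global severity

The eight NIH organ scores (0–3) are inputs; the per-organ scoring
rubrics are out of scope here. Global severity is *severe* when any
organ scores 3 or the lung scores ≥2; *moderate* when the lung scores 1,
any organ scores 2, or three or more organs score 1; *mild* for one or
two non-lung organs at 1; *none* otherwise. A lung score of 3 is treated
as severe (the lung-2 rule is a lower trigger, not a cap). When three
organs score 1 and one of them is the lung, the organ is counted once —
the lung-1 rule already forces moderate, so the reading has no effect on
the label. The suite checks all 4⁸ = 65,536 score vectors against an
independently written closed-form predicate, plus monotonicity and the
metamorphic invariances (Karnofsky and "undefined other" manifestations
never alter the label; non-GvHD attribution equals zeroing).

Input-selection rules: the lung score comes from pulmonary function
tests when recent — default staleness window 183 days, the permissive
end of the recommended 3–6 months, configurable — otherwise from the
symptomatic dyspnea score, with the source always recorded. Weight loss
is limited to the trailing 3 calendar months; the baseline is the
nearest measurement at or before the window start, with no interpolation
(reproducibility over smoothness), the result is floored at 0, and a
missing baseline yields "not evaluable", never 0. Severity markers that
are therapeutic interventions (punctal plugs, esophageal dilatation) are
stored as dated intervention records; whether they inform scoring is a
protocol decision, defaulting to interventions within the last 12
months.

## Course classification

Day 100 is counted from the transplant or the last donor lymphocyte
infusion, whichever happened last, in whole days, with "classic" onset
at day ≤ 100 (the table prints "≤Day 100"). Activity is *active*
whenever inflammatory or worsening manifestations are present,
regardless of treatment; otherwise *controlled* on immunosuppression or
off it for less than 12 (acute) / 24 (chronic) weeks; beyond the window,
*inactive* with fixed sequelae and *resolved* without. The printed rule
says "less than" for controlled and "more than" for the off-treatment
labels with no equality clause; equality at the boundary leaves
controlled (12 whole weeks off is already resolved/inactive). "Flare" is
accepted as an input alias but always re-emitted as
recurrence/progression. A patient never given systemic
immunosuppression counts time off treatment from the end of activity
(resolution without treatment).

Steroid-response definitions ship as named variants
(`inst/config/steroid_variants.yaml`) because the cited windows genuinely
differ: acute progression within 3, 4 or 5 days on ≥2 mg/kg/day
prednisone equivalent; failure to improve within 5–7 days; incomplete
response beyond 28 days; chronic progression on ≥1 mg/kg/day over 1–2
weeks; stable disease on ≥0.5 mg/kg/day over 1–2 months. The consensus
default takes the long end of each printed range (5 days, 7 days,
14 days, 2 months) — the most specific reading, labelling fewest
patients refractory — and excludes the 14-day trial-eligibility
definition, which is shipped as the `trial_14d` preset. Chronic
dependence is loss of control at or below the 0.25 mg/kg/day taper
floor in at least two attempts at least 8 weeks apart; the floor is
inclusive — failing while attempting to go below 0.25 means failing at
the floor itself, so a trial dose of exactly 0.25 marks dependence.
Acute dependence is the inability to taper below 2 mg/kg/day after at
least 7 days of initially successful treatment, or recurrence during
the taper (detected as progression at a dose below the previous
maximum, after improvement). Non-prednisone steroids convert through a
shipped equivalence table; the methylprednisolone factor (1.25) is an
extrapolation and is marked as such. Classification precedence is
refractory, dependent, intolerant, responsive; with no failure clause
and no recorded improvement the episode is not evaluable, with a
reason.

## The synthetic cohort generator

`generate_cohort()` is constructive and label-first: labels are drawn
from the configured mixes, then dates, findings, doses and response
series are built to satisfy them (a quiescent-onset patient's acute
activity ends before the chronic onset; a persistent late-acute patient
stays active past day 100 with no chronic disease; organ findings are
representative values inside the assigned MAGIC stage bands). One seeded
RNG stream per cohort makes regeneration byte-identical. Infeasible
combinations (persistent acute requires absence of chronic GvHD; de novo
chronic requires absence of prior acute) are resolved by redrawing from
the renormalized feasible mix, and a mix with no feasible mass raises an
error. Default mixes spread the taxonomy roughly evenly with a 40%
chronic fraction and a 15% pediatric fraction — chosen to exercise every
classifier branch, not to model GvHD epidemiology.

What passing label-recovery tests shows, and what it does not: the
generator emits records whose classifications are unambiguous by
construction, so 100% recovery demonstrates that the engine inverts the
taxonomy correctly; it says nothing about measurement noise, missing
data, disagreeing assessors, or the mixed-etiology judgment calls of
real records, which enter this engine only through the attribution
flags.

## Problem sizes and runtime choices

The enumeration surfaces are exact and small: 250 acute stage tuples ×
5 systems (original Glucksberg swept over a grid of Karnofsky values),
65,536 chronic score vectors, 24 boundary fixtures at ±1 unit around
every printed threshold, and a 500-trajectory seeded cohort for label
recovery; the full suite runs in about a minute on one CPU. The
acceptance script re-derives each printed threshold by scanning the
relevant function over a fine grid (e.g. bilirubin in 0.1 μmol/L steps,
taper doses in 0.01 mg/kg/day steps) and reporting the exact flip point.

## Known limitations

The engine grades what it is given: per-organ NIH scores, response
labels (CR/PR/progression) and attribution judgments are inputs, and the
NIH/MAGIC response criteria that define them are out of scope.
Histopathology interpretation, biomarkers and treatment recommendations
are likewise out of scope. The original-Glucksberg Karnofsky mapping and
the methylprednisolone factor are documented extrapolations; the printed
sources do not fix them. Legacy Seattle categories are computed from
declared categorical findings, not re-derived from organ scores.
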