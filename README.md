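# gvhdgrade

Consensus grading and course classification of graft-versus-host disease
(GvHD) after allogeneic hematopoietic cell transplantation (HCT), as a
validated rule engine over longitudinal patient records.

GvHD assessment in practice mixes several published systems whose printed
thresholds differ in consequential ways, and misclassification is common
even at experienced centers. This package implements the published rules
exactly, with a traceable rationale for every label, for transplant
clinicians, trialists and registry data managers who need reproducible
grading rather than bedside recollection of the tables.

## What it computes

**Acute GvHD.** Per-organ staging from raw findings — skin by % body
surface area (BSA) of rash (stage 1: <25%, 2: 25–50%, 3: >50%; stage 4
generalized erythroderma, under MAGIC with bullae/desquamation ≥5% BSA);
liver by total serum bilirubin (<2 / 2–3 / 3.1–6 / 6.1–15 / >15 mg/dL,
equivalently >255 μmol/L for stage 4); upper GI by persistent
anorexia/nausea/vomiting (nausea ≥3 days, or vomiting ≥2 episodes/day for
≥2 days); lower GI by stool volume or episode count (MAGIC adult bands
<500 / 500–999 / 1000–1500 / >1500 mL/day and <3 / 3–4 / 5–7 / >7
episodes/day, per-kg bands for children under 50 kg, stage = max of the
two sub-stages; severe abdominal pain ± ileus or grossly bloody stools →
stage 4). Overall grade 0–IV (or IBMTR A–D) under each of five systems:
MAGIC, Keystone (modified Glucksberg), Minnesota, IBMTR and original
Glucksberg, plus the MAGIC diagnostic-confidence level
(confirmed/probable/possible/negative).

**Chronic GvHD.** NIH 2014 global severity over eight organ scores
s₁…s₈ ∈ {0,1,2,3}: *severe* if any sᵢ = 3 or lung ≥ 2; *moderate* if
lung = 1, any sᵢ = 2, or ≥3 organs at 1; *mild* for 1–2 non-lung organs
at 1; *none* otherwise. Lung score source selection (recent PFT vs
symptomatic dyspnea), the trailing 3-month weight-loss window, and the
legacy original/revised Seattle limited/extensive categories.

**Course.** GvHD type (acute / classic chronic / overlap chronic /
undefined other), acute onset (classic ≤ day 100 from HCT or last DLI /
late / recurrent / persistent), chronic onset (de novo / quiescent /
progressive — always overlap), activity (active / controlled / inactive /
resolved, with the 12-week acute and 24-week chronic off-immunosuppression
windows), and steroid response (refractory / dependent / intolerant /
responsive) under named definition variants.

Non-GvHD attribution excludes an organ from every overall score;
Karnofsky performance status and "undefined other" manifestations are
recorded but never scored (Karnofsky enters only the original Glucksberg
grade).

## Worked example

```r
library(gvhdgrade)

visit <- tibble::tibble(rash_bsa_pct = 60, bilirubin_mg_dl = 4.2,
                        nausea_days = 4, stool_volume_ml_per_day = 1200)
grade_acute(stage_acute(visit, system = "magic"), system = "magic")
#>   skin_stage liver_stage upper_gi_stage lower_gi_stage system grade
#> 1          3           2              1              2 magic  III
```

Rash of 60% BSA is skin stage 3; bilirubin 4.2 mg/dL falls in the 3.1–6
band (liver 2); four days of nausea is persistent (upper GI 1); 1200
mL/day of diarrhea is lower GI 2 — and liver or lower GI at stage 2–3 is
overall grade III under MAGIC. The scalar interface shows which rows
fired:

```r
overall_acute_grade(3, 2, 1, 2, system = "magic")
#> Acute GvHD overall grade III [magic]
#>   stages: skin 3, liver 2, upper GI 1, lower GI 2
#>   rules: magic.III.liver; magic.III.lower_gi

nih_global_severity(c(skin = 1, lungs = 1))
#> NIH 2014 chronic GvHD global severity: moderate
#>   organ scores: skin 1, lungs 1
#>   rules: nih.moderate.lung_1

steroid_response(data.frame(day = 0, dose_mg_kg_day = 2.5),
                 data.frame(day = 4, label = "progression"), "acute")
#> Steroid response (acute GvHD, variant consensus): refractory
#>   rationale: acute.refractory.progression_within_5d_on_ge2mgkg
```

Rule ids reference the reviewable rules file shipped at
`inst/rules/acute_overall.yaml`; steroid definition variants live in
`inst/config/steroid_variants.yaml`.

Cohort-scale surfaces: `generate_cohort(cohort_config(seed, n))` builds
seeded synthetic patients with constructive ground-truth labels,
`compare_systems(stage_grid())` summarises cross-system agreement
(`tidy()`, `glance()`, `autoplot()` methods), and JSON patient records
round-trip through `read_patient_record()` / `write_patient_record()`
with schema validation (`inst/schema/patient-record-v1.json`). A thin
CLI wraps these as `exec/gvhd validate|acute|chronic|course|report|synth|
concordance`.

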