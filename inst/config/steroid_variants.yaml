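# Steroid-response definition presets. "consensus" is the engine default;
# the other presets select the alternative cited windows. All doses are
# prednisone-equivalent mg/kg/day; windows are days.
consensus:
  description: >
    Default consensus definitions: acute progression within 5 days on
    >=2 mg/kg/day, failure to improve within 7 days, incomplete response
    beyond 28 days; chronic progression on >=1 mg/kg/day over 2 weeks or
    stable disease on >=0.5 mg/kg/day over 2 months; dependence floors
    2 (acute) and 0.25 (chronic) mg/kg/day, two chronic taper failures at
    least 8 weeks apart.
  active_clauses: [progression, no_improvement, late_incomplete]
  acute_progression_window_days: 5
  acute_progression_min_dose: 2
  acute_improvement_window_days: 7
  acute_late_assessment_days: 28
  acute_dependence_taper_floor: 2
  acute_dependence_min_success_days: 7
  chronic_progression_min_dose: 1
  chronic_progression_window_days: 14
  chronic_stable_min_dose: 0.5
  chronic_stable_window_days: 60
  chronic_dependence_floor: 0.25
  chronic_dependence_min_attempts: 2
  chronic_dependence_separation_days: 56
refractory_3d:
  description: Acute progression clause evaluated within 3 days of therapy onset.
  acute_progression_window_days: 3
refractory_4d:
  description: Acute progression clause evaluated within 4 days of therapy onset.
  acute_progression_window_days: 4
refractory_5_7d:
  description: >
    Acute progression within 5 days; failure to improve within 7 days.
  acute_progression_window_days: 5
  acute_improvement_window_days: 7
refractory_28d:
  description: >
    Late-assessment clause only - incomplete response after more than 28
    days of immunosuppressive treatment including steroids.
  active_clauses: [late_incomplete]
trial_14d:
  description: >
    Trial-eligibility definition - incomplete response after 14 days of
    therapy. Shipped for completeness; excluded from the consensus default.
  active_clauses: [progression, no_improvement, late_incomplete]
  acute_late_assessment_days: 14
chronic_1mo:
  description: Chronic stable-disease clause evaluated over 1 month (30 days).
  chronic_stable_window_days: 30
chronic_2mo:
  description: Chronic stable-disease clause evaluated over 2 months (60 days).
  chronic_stable_window_days: 60
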