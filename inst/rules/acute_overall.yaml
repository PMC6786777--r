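# Reviewable serialization of the overall acute GvHD grade rules applied by
# the engine. Rule ids here are the ids emitted in `rule_trace`.
# Stages: skin 0-4, liver 0-4, upper_gi 0-1, lower_gi 0-4. Grading is the
# highest grade whose clause fires; organs attributed solely to a non-GvHD
# cause are excluded (set to 0) first and traced as
# exclude.<organ>.non_gvhd_only.
magic:
  - id: magic.0.all_organs_0
    grade: "0"
    when: all included organs stage 0
  - id: magic.I.skin1-2
    grade: I
    when: skin 1-2, no liver/GI involvement
  - id: magic.II.skin3
    grade: II
    when: skin 3
  - id: magic.II.liver1
    grade: II
    when: liver 1
  - id: magic.II.upper_gi1
    grade: II
    when: upper GI 1
  - id: magic.II.lower_gi1
    grade: II
    when: lower GI 1
  - id: magic.III.liver
    grade: III
    when: liver 2-3
  - id: magic.III.lower_gi
    grade: III
    when: lower GI 2-3
  - id: magic.IV.skin4
    grade: IV
    when: skin 4
  - id: magic.IV.liver4
    grade: IV
    when: liver 4
  - id: magic.IV.lower_gi4
    grade: IV
    when: lower GI 4
keystone:
  - id: keystone.0.all_organs_0
    grade: "0"
    when: all included organs stage 0
  - id: keystone.I.skin1-2
    grade: I
    when: skin 1-2, no liver/GI involvement
  - id: keystone.II.skin3
    grade: II
    when: skin 3
  - id: keystone.II.liver1
    grade: II
    when: liver 1
  - id: keystone.II.upper_gi1
    grade: II
    when: upper GI 1 (histology-proven persistent nausea)
  - id: keystone.II.lower_gi1
    grade: II
    when: lower GI 1
  - id: keystone.III.liver
    grade: III
    when: liver 2-3
  - id: keystone.III.lower_gi
    grade: III
    when: lower GI 2-4
  - id: keystone.IV.skin4
    grade: IV
    when: skin 4
  - id: keystone.IV.liver4
    grade: IV
    when: liver 4
minnesota:
  - id: minnesota.0.all_organs_0
    grade: "0"
    when: all included organs stage 0
  - id: minnesota.I.skin1-2
    grade: I
    when: skin 1-2, no liver/GI involvement
  - id: minnesota.II.skin3
    grade: II
    when: skin 3
  - id: minnesota.II.liver1
    grade: II
    when: liver 1
  - id: minnesota.II.upper_gi1
    grade: II
    when: upper GI 1
  - id: minnesota.II.lower_gi1
    grade: II
    when: lower GI 1
  - id: minnesota.III.liver
    grade: III
    when: liver 2-4
  - id: minnesota.III.lower_gi
    grade: III
    when: lower GI 2-3
  - id: minnesota.IV.skin4
    grade: IV
    when: skin 4
  - id: minnesota.IV.lower_gi4
    grade: IV
    when: lower GI 4
ibmtr:
  - id: ibmtr.0.all_organs_0
    grade: "0"
    when: all included organs stage 0
  - id: ibmtr.A.skin1
    grade: A
    when: skin 1, no liver/GI involvement
  - id: ibmtr.B.skin2
    grade: B
    when: skin 2
  - id: ibmtr.B.liver1-2
    grade: B
    when: liver 1-2
  - id: ibmtr.B.lower_gi1-2
    grade: B
    when: lower GI 1-2 (upper GI not graded; lower-GI-only reading)
  - id: ibmtr.C.skin3
    grade: C
    when: skin 3
  - id: ibmtr.C.liver3
    grade: C
    when: liver 3
  - id: ibmtr.C.lower_gi3
    grade: C
    when: lower GI 3
  - id: ibmtr.D.skin4
    grade: D
    when: skin 4
  - id: ibmtr.D.liver4
    grade: D
    when: liver 4
  - id: ibmtr.D.lower_gi4
    grade: D
    when: lower GI 4
glucksberg_original:
  - id: glucksberg_original.0.all_organs_0
    grade: "0"
    when: all included organs stage 0
  - id: glucksberg_original.karnofsky_bands.extrapolated
    grade: null
    when: >
      performance-status decreases mapped to Karnofsky bands (mild <90,
      marked <70, grade IV <30) - an extrapolation, always traced
  - id: glucksberg_original.I.any_involvement_floor
    grade: I
    when: >
      any organ involvement not matching a higher row (floor preserving
      grade-0 equivalence; extrapolated beyond the printed skin-only row)
  - id: glucksberg_original.II.skin_plus_visceral_mild_ps
    grade: II
    when: skin 1-2 with liver and/or GI 1-2 and mild performance decrease
  - id: glucksberg_original.III.stage2plus_marked_ps
    grade: III
    when: any organ 2-4 with marked performance decrease
  - id: glucksberg_original.IV.stage2plus_karnofsky_lt30
    grade: IV
    when: any organ 2-4 with Karnofsky below 30 percent
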