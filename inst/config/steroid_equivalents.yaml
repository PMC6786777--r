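# Prednisone-equivalence factors for systemic corticosteroids.
# The methylprednisolone factor is an extrapolation from common potency
# tables (4 mg methylprednisolone ~ 5 mg prednisone), not a consensus value.
factors:
  prednisone: 1.0
  prednisolone: 1.0
  methylprednisolone: 1.25
notes:
  methylprednisolone: extrapolated potency ratio; marked in rationale output
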