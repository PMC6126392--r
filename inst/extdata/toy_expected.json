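{
  "tally": {
    "n_input": 26,
    "removed_contaminant": 1,
    "removed_reverse": 1,
    "removed_missed_cleavage": 1,
    "removed_multi_label_site": 1,
    "identification_only": 1,
    "kinetic": 21
  },
  "status": {
    "P_FEW": "TOO_FEW_POINTS",
    "P_NOLATE": "MISSING_LATE_POINTS",
    "P_IMP": "IMPOSSIBLE_PROFILE",
    "P_ART": "PASS",
    "P_SEC": "PASS",
    "P_LEAK": "PASS"
  },
  "artifact_flagged": "P_ART",
  "n_unflagged_fitted": 2,
  "k": {
    "P_SEC": 0.2,
    "P_LEAK": 0.005
  }
}
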