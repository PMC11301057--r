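{
  "package": "faersignal",
  "version": "0.1.0",
  "started": "2026-10-02T02:14:02+0000",
  "config": {
    "input_dir": "/tmp/RtmpeQDIc0/fixture_in_46c50ca7518",
    "drug_terms": ["TRIFLURIDINE/TIPIRACIL", "TAS102", "FTD/TPI", "LONSURF"],
    "roles": "PS",
    "criteria": {
      "min_a": 3,
      "ror_ci_low": 1,
      "prr_min": 2,
      "chi2_min": 4,
      "ic025_min": 0,
      "eb05_min": 2,
      "rule": "all",
      "n_required": 4,
      "yates": false
    },
    "age_cuts": [18, 65],
    "min_cohort": 2,
    "tto_breaks": [30, 60, 90, 180, 365]
  },
  "counts": {
    "reports_read": 12,
    "duplicates_removed": 2,
    "deduplicated_reports": 10,
    "cohort_reports": 5,
    "background_reports": 5,
    "pt_pairs": 15,
    "unmapped_pts": 1,
    "pt_terms": 4,
    "soc_terms": 3,
    "retained_pt": 0,
    "retained_soc": 0,
    "tto": {
      "included": 2,
      "excluded_missing": 1,
      "excluded_partial_date": 1,
      "excluded_event_before_start": 1
    }
  },
  "tto_summary": {
    "median": 50,
    "q1": 47,
    "q3": 53
  },
  "subgroup_exclusions": {
    "sex": [
      {
        "stratum": "missing",
        "cohort_n": 1,
        "reason": "cohort below floor of 2 reports"
      }
    ],
    "age": [
      {
        "stratum": "<18",
        "cohort_n": 1,
        "reason": "cohort below floor of 2 reports"
      }
    ]
  },
  "finished": "2026-10-02T02:14:03+0000"
}
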