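# Example run configuration. Every field is optional; omitted fields take
# the package defaults shown here.
phenotype:
  hba1c_threshold: 6.5        # percent; abnormal at or above
  fasting_threshold: 126      # mg/dL
  random_threshold: 200       # mg/dL
  onset_window: 1095          # days: "within three years"
  type1_precedence: 365       # days a type 1 code must trail the first type 2 code
  med_exclusion_lead: 30      # days of antidiabetic treatment before onset that exclude
  min_age_years: 30
  study_start: 1995-01-01
  study_end: 2009-12-31
  med_anchor: onset           # or "code"
  exclude_probable_undiagnosed: false
matching:
  ratio: 5
  # birth_cuts: [1925, 1935, 1945, 1955]   # omit to use case birth-year quintiles
  min_observation_days: 60
  engagement_years: 3
  engagement_include_reference_year: false
  gap_years: 4
followup_end: 2011-12-31
seed: 1
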