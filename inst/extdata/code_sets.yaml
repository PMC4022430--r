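# Default ICD-9 code sets, in the package's wildcard syntax ("X" matches
# one digit; the dot is ignored when matching). Edit and pass through the
# run-config YAML under `code_sets:` to override any set.
type2: ["250.X0", "250.X2"]
type1: ["250.X1", "250.X3"]
diabetes_related: ["250.X0", "250.X2", "357.2", "362.0X", "583.81"]
breast_cancer: ["174", "174.X", "175", "175.X"]
prostate_cancer: ["185"]
colon_cancer: ["153", "153.X"]
myocardial_infarction: ["410.XX", "410.X", "412"]
coronary_heart_disease: ["414.XX", "414.X", "411.XX", "411.X", "413.X"]
peripheral_vascular: ["443.X", "440.XX", "440.X", "441.XX", "441.X"]
cardiovascular_disease: ["430", "431", "432.X", "433.XX", "434.XX", "435.X", "436", "437.X", "438.XX", "438.X"]
chronic_pulmonary: ["490", "491.XX", "491.X", "492.X", "493.XX", "493.X", "494", "495.X", "496"]
rheumatic_heart: ["393", "394.X", "395.X", "396.X", "397.X", "398.XX", "398.X"]
renal_disease: ["585", "585.X", "586", "582.X", "582.XX"]
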