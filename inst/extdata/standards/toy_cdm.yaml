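name: toy_cdm
description: >
  Toy clinical common data model used for tests and examples. Synthetic:
  a small stand-in for production cancer-research data models, with a
  handful of enumerated clinical attributes and free numeric attributes.
attributes:
  - name: gender
    description: Self-reported gender of the participant.
    values: [female, male, unknown]
    metadata: {type: text}
  - name: race
    description: Self-reported race of the participant.
    values: [white, black or african american, asian, other, not reported]
    metadata: {type: text}
  - name: ethnicity
    description: Self-reported ethnicity of the participant.
    values: [hispanic or latino, not hispanic or latino, not reported]
    metadata: {type: text}
  - name: vital_status
    description: Survival state of the participant at last follow-up.
    values: [alive, dead, not reported]
    metadata: {type: text}
  - name: tumor_focality
    description: Whether the tumor is unifocal or multifocal.
    values: [unifocal, multifocal]
    metadata: {type: text}
  - name: tumor_grade
    description: Histologic grade of the tumor.
    values: [g1, g2, g3, g4, gx]
    metadata: {type: text}
  - name: primary_diagnosis
    description: Diagnosis term for the primary tumor.
    values: [renal cell carcinoma, endometrial carcinoma, adenocarcinoma]
    metadata: {type: text}
  - name: cnv_status
    description: Copy-number variation burden class of the tumor sample.
    values: [CNV_L, CNV_H]
    metadata: {type: text}
  - name: bmi
    description: Body mass index of the participant in kg/m2.
    values: []
    metadata: {type: numeric, unit: kg/m2}
  - name: age_at_diagnosis
    description: Age at the time of diagnosis, expressed in days.
    values: []
    metadata: {type: numeric, unit: days}
  - name: age_at_index
    description: Age at the index date, expressed in years.
    values: []
    metadata: {type: numeric, unit: years}
  - name: country_of_birth
    description: Country where the participant was born.
    values: []
    metadata: {type: text}
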