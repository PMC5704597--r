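# Default predictor registry: name, kind (numeric|categorical), direction,
# threshold (damaging-inclusive), label map for categorical predictors,
# family, and whether a publicly recommended threshold exists.
# Thresholds follow common dbNSFP / author-recommended defaults and are
# deliberately user-editable; analyses log the values in force.
- name: SIFT
  kind: numeric
  direction: lower_damaging
  threshold: 0.05
  family: function
  has_public_threshold: true
- name: Polyphen2_HDIV
  kind: categorical
  labels: {D: damaging, P: damaging, B: tolerated}
  family: function
  has_public_threshold: true
- name: Polyphen2_HVAR
  kind: categorical
  labels: {D: damaging, P: damaging, B: tolerated}
  family: function
  has_public_threshold: true
- name: LRT
  kind: categorical
  labels: {D: damaging, N: tolerated, U: NA}
  family: function
  has_public_threshold: true
- name: MutationTaster
  kind: categorical
  labels: {A: damaging, D: damaging, N: tolerated, P: tolerated}
  family: function
  has_public_threshold: true
- name: MutationAssessor
  kind: categorical
  labels: {H: damaging, M: damaging, L: tolerated, N: tolerated}
  family: function
  has_public_threshold: true
- name: FATHMM
  kind: numeric
  direction: lower_damaging
  threshold: -1.5
  family: function
  has_public_threshold: true
- name: PROVEAN
  kind: numeric
  direction: lower_damaging
  threshold: -2.5
  family: function
  has_public_threshold: true
- name: fathmm-MKL
  kind: numeric
  direction: higher_damaging
  threshold: 0.5
  family: function
  has_public_threshold: true
- name: MetaSVM
  kind: numeric
  direction: higher_damaging
  threshold: 0.0
  family: metapredictor
  has_public_threshold: true
- name: MetaLR
  kind: numeric
  direction: higher_damaging
  threshold: 0.5
  family: metapredictor
  has_public_threshold: true
- name: M-CAP
  kind: numeric
  direction: higher_damaging
  threshold: 0.025
  family: metapredictor
  has_public_threshold: true
- name: CADD
  kind: numeric
  direction: higher_damaging
  threshold: 15
  family: metapredictor
  has_public_threshold: true
- name: VEST3
  kind: numeric
  direction: higher_damaging
  threshold: 0.5
  family: metapredictor
  has_public_threshold: true
- name: REVEL
  kind: numeric
  direction: higher_damaging
  threshold: 0.5
  family: metapredictor
  has_public_threshold: true
- name: Condel
  kind: numeric
  direction: higher_damaging
  threshold: 0.469
  family: metapredictor
  has_public_threshold: true
- name: DANN
  kind: numeric
  direction: higher_damaging
  threshold: 0.98
  family: metapredictor
  has_public_threshold: true
- name: MutPred
  kind: numeric
  direction: higher_damaging
  threshold: 0.5
  family: function
  has_public_threshold: true
- name: GERP++
  kind: numeric
  direction: higher_damaging
  family: conservation
  has_public_threshold: false
- name: phyloP
  kind: numeric
  direction: higher_damaging
  family: conservation
  has_public_threshold: false
- name: phastCons
  kind: numeric
  direction: higher_damaging
  family: conservation
  has_public_threshold: false
- name: SiPhy
  kind: numeric
  direction: higher_damaging
  family: conservation
  has_public_threshold: false
- name: Eigen
  kind: numeric
  direction: higher_damaging
  family: metapredictor
  has_public_threshold: false
- name: GenoCanyon
  kind: numeric
  direction: higher_damaging
  family: conservation
  has_public_threshold: false
- name: fitCons
  kind: numeric
  direction: higher_damaging
  family: conservation
  has_public_threshold: false
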