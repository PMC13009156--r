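# Base-case model inputs for PRS-guided CAD prevention in children:
# one entry per parameter with its base value, units, and the probability
# distribution used by the probabilistic sensitivity analysis.
# Regenerate with: write_parameter_set(default_parameters(), path)
parameters:
- name: cad_incidence_10y_top20
  base_value: 0.12
  units: probability
  distribution:
    kind: beta
    alpha: 120.0
    beta: 880.0
  note: 10-year CAD incidence, top 20% PRS
- name: stroke_incidence_10y_top20
  base_value: 0.12
  units: probability
  distribution:
    kind: beta
    alpha: 120.0
    beta: 880.0
  note: 10-year stroke incidence, top 20% PRS (assumed equal to CAD)
- name: relative_risk_reduction
  base_value: 0.29999999999999999
  units: fraction
  distribution:
    kind: lognormal_rr
    meanlog: -0.35667494393873245
    sdlog: 0.073389632340436
  note: uniform RRR of preventive intervention; RR median 0.70, 95% CI 0.60-0.80
- name: utility_10_40
  base_value: 0.94999999999999996
  units: utility
  distribution:
    kind: normal
    mean: 0.94999999999999996
    sd: 0.02
  note: utility, age 10-40
- name: utility_40_60
  base_value: 0.92000000000000004
  units: utility
  distribution:
    kind: normal
    mean: 0.92000000000000004
    sd: 0.03
  note: utility, age 40-60
- name: utility_60plus
  base_value: 0.84999999999999998
  units: utility
  distribution:
    kind: normal
    mean: 0.84999999999999998
    sd: 0.04
  note: utility, age >60
- name: cad_fatality
  base_value: 0.20000000000000001
  units: probability
  distribution:
    kind: beta
    alpha: 100.0
    beta: 400.0
  note: acute CAD case fatality
- name: stroke_fatality
  base_value: 0.20000000000000001
  units: probability
  distribution:
    kind: beta
    alpha: 100.0
    beta: 400.0
  note: acute stroke case fatality (assumed equal to CAD)
- name: qaly_loss_fatal_cad
  base_value: 12.40000000000000036
  units: QALY
  distribution:
    kind: normal
    mean: 12.40000000000000036
    sd: 1.19999999999999996
  note: QALY loss per fatal CAD event
- name: qaly_loss_fatal_stroke
  base_value: 12.40000000000000036
  units: QALY
  distribution:
    kind: normal
    mean: 12.40000000000000036
    sd: 1.19999999999999996
  note: QALY loss per fatal stroke event (assumed equal to CAD)
- name: genetic_test_cost
  base_value: 400.0
  units: USD-2024
  distribution:
    kind: gamma
    shape: 24.99999999999999645
    scale: 16.00000000000000355
  note: one-time genetic testing + counseling + lifestyle program, per child
- name: statin_monitoring_annual_cost
  base_value: 250.0
  units: USD-2024
  distribution:
    kind: gamma
    shape: 24.99999999999999645
    scale: 10.00000000000000178
  note: annual statin + monitoring, top 2% PRS
- name: lifetime_cad_cost
  base_value: 421487.0
  units: USD-2024
  distribution:
    kind: gamma
    shape: 16.0
    scale: 26342.9375
  note: lifetime direct CAD cost per case
- name: lifetime_stroke_cost
  base_value: 421487.0
  units: USD-2024
  distribution:
    kind: gamma
    shape: 16.0
    scale: 26342.9375
  note: lifetime direct stroke cost per case (assumed equal to CAD)
- name: discount_rate
  base_value: 0.03
  units: rate
  distribution:
    kind: fixed
    value: 0.03
  note: annual discounting
- name: medical_inflation
  base_value: 0.05
  units: rate
  distribution:
    kind: fixed
    value: 0.05
  note: projected annual healthcare cost inflation
- name: qaly_monetary_value
  base_value: 100000.0
  units: USD-2024
  distribution:
    kind: fixed
    value: 100000.0
  note: monetary value per QALY
- name: productivity_per_case
  base_value: 200000.0
  units: USD-2024
  distribution:
    kind: fixed
    value: 200000.0
  note: productivity savings per prevented case
- name: cobenefit_multiplier
  base_value: 0.14999999999999999
  units: fraction
  distribution:
    kind: fixed
    value: 0.14999999999999999
  note: indirect health co-benefit multiplier
- name: qaly_gain_per_case
  base_value: 13.30000000000000071
  units: QALY
  distribution:
    kind: fixed
    value: 13.30000000000000071
  note: QALYs gained per prevented case
- name: cohort_size
  base_value: 10000.0
  units: count
  distribution:
    kind: fixed
    value: 10000.0
  note: children entering the model at age 10
- name: high_risk_fraction
  base_value: 0.20000000000000001
  units: fraction
  distribution:
    kind: fixed
    value: 0.20000000000000001
  note: top PRS quantile receiving lifestyle intervention
- name: very_high_risk_fraction
  base_value: 0.02
  units: fraction
  distribution:
    kind: fixed
    value: 0.02
  note: top PRS quantile additionally receiving statins
- name: horizon_years
  base_value: 30.0
  units: year
  distribution:
    kind: fixed
    value: 30.0
  note: medication / adjustment horizon
- name: statin_annuity_printed
  base_value: 19.39999999999999858
  units: factor
  distribution:
    kind: fixed
    value: 19.39999999999999858
  note: published discounted 30-year medication PV per $1 annual cost
- name: screening_unit_cost
  base_value: 250.0
  units: USD-2024
  distribution:
    kind: fixed
    value: 250.0
  note: cost per cardiovascular screen (schedule reconstruction)
- name: screening_end_age
  base_value: 70.0
  units: year
  distribution:
    kind: fixed
    value: 70.0
  note: screening stops at this age
- name: screening_start_high
  base_value: 40.0
  units: year
  distribution:
    kind: fixed
    value: 40.0
  note: intensive screening start age, high-PRS group
- name: screening_start_low
  base_value: 50.0
  units: year
  distribution:
    kind: fixed
    value: 50.0
  note: routine screening start age, remainder of cohort
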