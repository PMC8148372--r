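# Base-case parameter registry for the dental-setting hypertension screening
# cost-effectiveness model. All costs in 2019 SEK.
cohort_size: 2025
cohort_men: 930
cohort_women: 1095
start_age: 53            # cohort mean age 52.8 rounded to a whole cycle age
discount_rate: 0.03      # annual, costs and QALYs alike; DSA range 0-0.05
horizon_years: 20
sek_per_eur: 10.3
unit_costs:
  dental_bp_test: 117
  phc_bp_test: 149
  ecg: 75
  lab: 240
  diagnosis: 785
  screening_admin: 165000    # fixed programme administration (30-40% FTE)
  ami_first_year: 112000
  post_ami_annual: 2670
  stroke_first_year: 112000
  post_stroke_annual: 85000
  drug_treatment_annual: 2150
  patient_time_hour: 160
  patient_travel_trip: 6.5
case_fatality_365d:          # probability of death within 365 days of event
  ami:
    men: 0.144
    women: 0.173
  stroke:
    men: 0.102
    women: 0.144
added_mortality_post365d:    # annual excess mortality beyond 365 days
  ami:
    men: 0.018
    women: 0.017
  stroke:
    men: 0.074
    women: 0.061
qaly_decrements:             # subtracted from the full-health weight of 1.0
  stroke_year: 0.50
  post_stroke: 0.25
  ami_year: 0.25
  post_ami: 0.05
sbp_untreated_hypertensive: 147
sbp_treated_hypertensive: 140
sbp_normotensive: 131
tc_hdl_ratio:
  men: 4.0
  women: 3.2
identified_cases_screening: 170
identified_cases_screening_se: 17
identified_cases_comparator_true: 46
comparator_false_positives: 15
comparator_total_diagnosed: 61
mi_share:                    # share of first coronary presentations that are MI
  men: 0.65
  women: 0.50
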