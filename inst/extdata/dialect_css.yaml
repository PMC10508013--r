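survey_id: css
column_map:
  household_id: caseid
  survey_id: survey
  wave_year: year
  urban: urban
  province: province
  family_size: fam_n
  income_total: hh_income
  consumption_total: hh_consumption
  food_expenditure: hh_food
  oop_health_expenditure: hh_oop_health
  weight: weight_cs
monthly_fields: []
notes: pure out-of-pocket health spending, outpatient + inpatient
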