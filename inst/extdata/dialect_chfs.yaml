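survey_id: chfs
column_map:
  household_id: hhid
  survey_id: survey
  wave_year: year
  urban: rural_urban
  province: prov_code
  family_size: hh_size
  income_total: total_income
  consumption_total: total_consumption
  food_expenditure: food_monthly
  oop_health_expenditure: health_exp
  weight: swgt
monthly_fields: food_expenditure
notes: food reported monthly; health spending includes exercise, supplements, fitness
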