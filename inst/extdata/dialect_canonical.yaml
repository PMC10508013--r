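survey_id: canonical
column_map:
  household_id: household_id
  survey_id: survey_id
  wave_year: wave_year
  urban: urban
  province: province
  family_size: family_size
  income_total: income_total
  consumption_total: consumption_total
  food_expenditure: food_expenditure
  oop_health_expenditure: oop_health_expenditure
  weight: weight
monthly_fields: []
notes: ''
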