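survey_id: cfps
column_map:
  household_id: fid
  survey_id: survey
  wave_year: year
  urban: urban
  province: provcd
  family_size: familysize
  income_total: fincome
  consumption_total: expense
  food_expenditure: food_month
  oop_health_expenditure: med_oop
  weight: fswt_natcs
monthly_fields: food_expenditure
notes: food reported monthly; OOP includes exercise and dietary supplements
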