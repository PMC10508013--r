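survey_id: cgss
column_map:
  household_id: id
  survey_id: survey
  wave_year: year
  urban: urban
  province: prov
  family_size: famsize
  income_total: inc_total
  consumption_total: cons_total
  food_expenditure: food_year
  oop_health_expenditure: health_oop
  weight: wt
monthly_fields: []
notes: food includes market value of home-grown farm products
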