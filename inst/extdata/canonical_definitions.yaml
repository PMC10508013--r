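che_definitions:
- denominator: nonfood_capacity
  threshold: 0.4
- denominator: total_consumption
  threshold: 0.1
- denominator: total_consumption
  threshold: 0.25
poverty_lines:
- kind: absolute
  base_usd_per_day: 1.9
  ppp_factor: 3.52
  cpi_factor: 1.13
  days_per_year: 365.0
- kind: absolute
  base_usd_per_day: 3.1
  ppp_factor: 3.52
  cpi_factor: 1.13
  days_per_year: 365.0
- kind: relative
  median_share: 0.6
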