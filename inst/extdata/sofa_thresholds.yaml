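# SOFA component cut-points, editable per site.
# Units: PF ratio mmHg, platelets 10^9/L, bilirubin/creatinine umol/L,
# vasopressor rates ug/kg/min, urine mL/day.
respiration:
  pf_cutpoints: [400.0, 300.0, 200.0, 100.0]   # strict <, one point each
  cap_without_ventilation: 2
coagulation:
  platelet_cutpoints: [150.0, 100.0, 50.0, 20.0]  # strict <
liver:
  bilirubin_min: [20.0, 33.0, 102.0]  # inclusive lower bounds for scores 1-3
  bilirubin_gt4: 204.0                # strict > for score 4
cardiovascular:
  map_lt: 70.0
  dopamine_mid: 5.0
  dopamine_high: 15.0
  norad_high: 0.1
cns:
  gcs_le: [14.0, 12.0, 9.0]
  gcs_lt4: 6.0
renal:
  creatinine_min: [110.0, 171.0, 300.0]
  creatinine_gt4: 440.0
  urine_lt3: 500.0
  urine_lt4: 200.0
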