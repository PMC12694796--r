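# Default indicator standards: internationally recommended thresholds and
# ranges for indoor air quality in exhibition spaces. Oscillation allowances
# (osc_low/osc_high, in the indicator's own units per day) and threshold
# saturation levels are package defaults; osc_fraction 0 keeps the published
# limits unwidened.
indicators:
- name: T
  unit: degC
  mode: range
  low: 16.0
  high: 24.0
  osc_fraction: 0.0
  osc_low: 1.0
  osc_high: 2.0
  source: ASHRAE guideline for museum collection spaces
- name: RH
  unit: '%'
  mode: range
  low: 45.0
  high: 60.0
  osc_fraction: 0.0
  osc_low: 3.0
  osc_high: 10.0
  source: ASHRAE guideline for museum collection spaces
- name: AL
  unit: lux
  mode: range
  low: 50.0
  high: 200.0
  osc_fraction: 0.0
  osc_low: 10.0
  osc_high: 50.0
  source: British Standards Institution guidance for rooms with valuable objects
- name: CO2
  unit: ppm
  mode: upper_threshold
  high: 1000.0
  osc_fraction: 0.0
  osc_low: 50.0
  osc_high: 200.0
  saturation: 2000.0
  source: ANSI/ASHRAE ventilation standard
- name: HCHO
  unit: mg/m3
  mode: upper_threshold
  high: 0.04
  osc_fraction: 0.0
  osc_low: 0.005
  osc_high: 0.02
  saturation: 0.08
  source: EPA indoor formaldehyde guideline
- name: TVOC
  unit: mg/m3
  mode: upper_threshold
  high: 1.0
  osc_fraction: 0.0
  osc_low: 0.05
  osc_high: 0.2
  saturation: 2.0
  source: WHO indoor air quality guideline
- name: PM2.5
  unit: ug/m3
  mode: upper_threshold
  high: 35.0
  osc_fraction: 0.0
  osc_low: 5.0
  osc_high: 15.0
  saturation: 70.0
  source: EPA particulate matter standard (daily)
- name: PM10
  unit: ug/m3
  mode: upper_threshold
  high: 35.0
  osc_fraction: 0.0
  osc_low: 5.0
  osc_high: 20.0
  saturation: 70.0
  source: EPA particulate matter standard (daily)
- name: I+
  unit: ions/cm3
  mode: upper_threshold
  high: 1000.0
  osc_fraction: 0.0
  osc_low: 100.0
  osc_high: 500.0
  saturation: 2000.0
  source: Air-ion exposure literature consensus
- name: I-
  unit: ions/cm3
  mode: lower_threshold
  low: 1000.0
  osc_fraction: 0.0
  osc_low: 100.0
  osc_high: 500.0
  saturation: 500.0
  source: Air-ion exposure literature consensus
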