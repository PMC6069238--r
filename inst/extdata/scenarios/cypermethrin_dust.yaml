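# Cypermethrin via ingestion of indoor dust, children 3-6 years.
compound: cypermethrin
route: indoor_dust
adi: 0.02      # mg/kg/day (WHO)
cf: 0.001      # g/mg
variables:
  ir:
    unit: mg/day
    kind: moments
    moments: {mean: 26.65, sd: 36.54, n: 1000}
    percentiles:
      probabilities: [0.05, 0.25, 0.50, 0.75, 0.95]
      values: [0.66, 4.06, 10.80, 28.72, 100.97]
    maximum: 901.96
  conc:
    unit: ug/g
    kind: moments
    lod: 0.031
    moments: {mean: 18.33, sd: 55.92, n: 52}
    percentiles:
      probabilities: [0.25, 0.50, 0.75, 0.95]
      values: [0.11, 0.37, 0.83, 105.79]
    maximum: 343.27
  bw:
    unit: kg
    kind: percentiles
    percentiles:
      probabilities: [0.03, 0.15, 0.25, 0.50, 0.75, 0.85, 0.97]
      values: [13.5, 15.1, 15.8, 17.3, 19.0, 20.1, 22.9]
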