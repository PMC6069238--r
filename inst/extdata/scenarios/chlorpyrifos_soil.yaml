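# Chlorpyrifos via ingestion of outdoor soil, children 3-6 years.
compound: chlorpyrifos
route: outdoor_soil
adi: 0.01      # mg/kg/day (WHO)
cf: 0.001      # g/mg
variables:
  ir:
    unit: mg/day
    kind: moments
    moments: {mean: 40.96, sd: 78.29, n: 1000}
    percentiles:
      probabilities: [0.05, 0.25, 0.50, 0.75, 0.95]
      values: [0.15, 5.26, 15.34, 44.85, 175.60]
    maximum: 1367.37
  conc:
    unit: ug/g
    kind: moments
    lod: 0.025
    moments: {mean: 4.27, sd: 23.10, n: 57}
    # P5-P50 are below the detection limit; only numeric percentiles listed.
    percentiles:
      probabilities: [0.75, 0.95]
      values: [0.11, 16.19]
    maximum: 134.60
  bw:
    unit: kg
    kind: percentiles
    percentiles:
      probabilities: [0.03, 0.15, 0.25, 0.50, 0.75, 0.85, 0.97]
      values: [13.5, 15.1, 15.8, 17.3, 19.0, 20.1, 22.9]
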