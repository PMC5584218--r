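# Demonstration pipeline configuration. Any key omitted here falls back
# to defaultPipelineConfig().
seed: 1
out: ptvrisk-demo
stages:
  simulate: true
  classify: true
  assoc: true
  enrich: true
  burden: false
  risk: true
  power: true
simulate:
  effects:
    - gene: GENE1
      f0: 0.0038
      or_hgs: 2.5
      or_other: 1.0
      recurrent_frac: 0.3
  incidence:
    targetRisk: 0.018
enrich:
  nPerm: 500
risk:
  or: 2.1
  se: 0.31
  carrierFreq: 0.0038
  level: 0.80
power:
  p0: 0.0038
  or: [3, 2]
  alpha: 1.0e-4
  sided: one
  power: 0.8
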