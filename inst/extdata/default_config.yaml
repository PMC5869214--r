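# Default configuration for the synthetic limited-data prioritization
# pipeline (see ?runPipeline). Any field omitted here keeps the package
# default; sizes are chosen so the full run completes in about two minutes
# on one core.
seed: 1
landscape:
  gridRows: 80
  gridCols: 80
  nCounties: 60
  nProvinces: 8
  autocorrelationLength: 8
envelope:
  forestClasses: 1
  precipMode: sum       # annual precipitation = sum of 12 monthly totals
historical:
  intercept: -2.5       # logit-scale; presence prob 7.6% at 0% suitable
  slopePerPercent: 0.1  # logit-scale increase per percentage point
randomization:
  nIterations: 10000
survey:
  respondentsPerCounty: 30
  baselineReportProb: 0.45
  effectProbDiff: 0.0
  provinceInterceptSD: 0.5
  countyOLRESD: 0.5
  countiesPerArm: 12
power:
  effectSizes: [0.0, 0.1]
  nReplicates: 20       # scaled-down demo; the power claim uses 200
  alpha: 0.05
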