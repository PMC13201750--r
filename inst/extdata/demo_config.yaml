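# Demo configuration: a small synthetic cohort at coarse resolution so the
# full pipeline completes in well under a minute.
outputDir: nigratarget_demo
seed: 101
nLeads: 40
voxelSize: 0.5
cvFolds: 5
confidence: 0.95
trainScenario: plus6mm
gpc:
  optimize: false
grid:
  "x": [1.0, 1.5, 2.0]
  "y": [-1.0, 0.0, 1.0]
  ms: [14, 18, 22, 26, 30]
  acpc: [38, 42, 46, 50, 54, 58, 62]
rulePanel:
  "x": 1.5
  "y": 0.0
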