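# Minimal single-population simulation config: constitutive maturation
# model with gamma noise on the transcription rate.
experiment: simulate
n_cells: 500
seed: 1
model: {network: M1}
params: {KN: 50, KM: 10}
noise:
  KN: {family: gamma, shape: 5, scale: 10}
  KM: {family: gamma, shape: 8, scale: 1.25}
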