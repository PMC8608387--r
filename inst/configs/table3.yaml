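# Two-stage model benchmark (M2, mRNA-protein pathway reporters vs dual
# mature-mRNA reporters). Kp ~ Gamma(5, 0.4) and deltaP ~ Gamma(8, 0.0125)
# in every row; rows vary the transcription-rate (Km) noise.
experiment: table3
replicates: 20
cells: 500
seed: 1
rows:
  - label: Km=50
    eta2_theory: 0.0
    kn: {family: point, value: 50}
  - label: Beta133.3(6,10.5)
    eta2_theory: 0.1
    kn: {family: scaled-beta, max: 133.3333333333, shape1: 6, shape2: 10.5}
  - label: Gamma(5,10)
    eta2_theory: 0.2
    kn: {family: gamma, shape: 5, scale: 10}
  - label: Beta300(1.5,7.5)
    eta2_theory: 0.5
    kn: {family: scaled-beta, max: 300, shape1: 1.5, shape2: 7.5}
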