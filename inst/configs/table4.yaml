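# Bursty four-stage model benchmark (M4): mean parameter rows
# (lambda, mu, KN, KP, deltaP); KM fixed at 10. Scaled Beta(5,6) noise
# (cv2 0.1) on lambda, mu, KP, deltaP; scaled Beta(3,6) noise (cv2 0.2)
# on KN, each scaled so the mean equals the row value.
experiment: table4
replicates: 20
cells: 500
seed: 1
rows:
  - {mean: {lambda: 0.5, mu: 1, KN: 150, KP: 2, deltaP: 0.1}}
  - {mean: {lambda: 1, mu: 2, KN: 150, KP: 2, deltaP: 0.1}}
  - {mean: {lambda: 1, mu: 20, KN: 1050, KP: 2, deltaP: 0.1}}
  - {mean: {lambda: 2, mu: 2, KN: 100, KP: 6, deltaP: 0.3}}
  - {mean: {lambda: 2, mu: 20, KN: 550, KP: 6, deltaP: 0.3}}
  - {mean: {lambda: 10, mu: 10, KN: 100, KP: 6, deltaP: 0.3}}
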