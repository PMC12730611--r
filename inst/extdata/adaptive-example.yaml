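# Example scenario: adaptive treatment with unknown patient parameters.
# gamma may be a positive scalar (meaning gamma * identity) or a 3x3
# matrix given as three rows.
name: adaptive-example
controller: adaptive
model:
  a: 1
  b: 2
  c: 9
gains:
  k1: 1.22
  k2: 10
adaptation:
  gamma: 0.1
init:
  state: [0.5, 0]
  estimate: [6, 2.5, 5]
sim:
  duration: 10
  step: 0.001
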