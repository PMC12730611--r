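# Example scenario: exact-model-knowledge treatment of the reference
# patient. All sections shown; `adaptation` and `init: estimate` are only
# required for controller: adaptive.
name: emk-example
controller: emk
model:
  a: 1
  b: 2
  c: 9
gains:
  k1: 1.1
  k2: 10
init:
  state: [0.5, 0]
sim:
  duration: 10
  step: 0.001
  method: rk4-fixed
  thin: 1
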