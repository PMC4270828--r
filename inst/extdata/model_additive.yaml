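functions:
  f1: ADD
  f2: ADD
  f3: ADD
  f4: ADD
  f5: ADD
  f6: ADD
loci:
  TF1:
    values:
    - 0.0
    - 1.0
    - 2.0
    probs:
    - 0.25
    - 0.5
    - 0.25
  TF2:
    values:
    - 0.0
    - 1.0
    - 2.0
    probs:
    - 0.25
    - 0.5
    - 0.25
  enhancer:
    values:
    - 0.0
    - 1.0
    - 2.0
    probs:
    - 0.25
    - 0.5
    - 0.25
  promoter:
    values:
    - 0.0
    - 1.0
    - 2.0
    probs:
    - 0.25
    - 0.5
    - 0.25
  coding:
    values:
    - 0.0
    - 1.0
    - 2.0
    probs:
    - 0.25
    - 0.5
    - 0.25
  microRNA:
    values:
    - 0.0
    - 1.0
    - 2.0
    probs:
    - 0.25
    - 0.5
    - 0.25
  environment:
    values:
    - -2.0
    - -1.0
    - 0.0
    - 1.0
    - 2.0
    probs:
    - 0.2
    - 0.2
    - 0.2
    - 0.2
    - 0.2
prevalence: 0.1
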