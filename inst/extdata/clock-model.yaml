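model: circadian-5gene
genes:
- index: 1
  name: Bmal1
  degradation: 0.25
  delay: 7.5
  production: 1.789845768789572
- index: 2
  name: Rev_erba
  degradation: 1.0
  delay: 0.5
  production: 0.836944633746997
- index: 3
  name: Per2
  degradation: 1.0
  delay: 3.82
  production: 1.752588446262807
- index: 4
  name: Cry1
  degradation: 0.2
  delay: 3.13
  production: 0.197602384440565
- index: 5
  name: Dbp
  degradation: 0.6
  delay: 1.0
  production: 0.941710299344764
exponents:
  activation: 3.0
  inhibition: 4.0
reference_means:
  Bmal1: 1.0
  Rev_erba: 1.0
  Per2: 1.0
  Cry1: 1.0
  Dbp: 1.0
regulations:
- source: Rev_erba
  target: Bmal1
  sign: inhibition
  strength: 0.075
- source: Bmal1
  target: Rev_erba
  sign: activation
  strength: 3.26
- source: Per2
  target: Rev_erba
  sign: inhibition
  strength: 0.040936481134588
- source: Cry1
  target: Rev_erba
  sign: inhibition
  strength: 0.582223263300213
- source: Dbp
  target: Rev_erba
  sign: activation
  strength: 3.441886041632151
- source: Bmal1
  target: Per2
  sign: activation
  strength: 1.282341557967144
- source: Per2
  target: Per2
  sign: inhibition
  strength: 0.97
- source: Cry1
  target: Per2
  sign: inhibition
  strength: 0.37
- source: Dbp
  target: Per2
  sign: activation
  strength: 1.541579016254175
- source: Bmal1
  target: Cry1
  sign: activation
  strength: 6.115037875215418
- source: Rev_erba
  target: Cry1
  sign: inhibition
  strength: 0.098845241046399
- source: Per2
  target: Cry1
  sign: inhibition
  strength: 0.866971420735543
- source: Cry1
  target: Cry1
  sign: inhibition
  strength: 0.298473882731954
- source: Dbp
  target: Cry1
  sign: activation
  strength: 2.762343888291037
- source: Bmal1
  target: Dbp
  sign: activation
  strength: 3.482472216718642
- source: Per2
  target: Dbp
  sign: inhibition
  strength: 0.506084274601988
- source: Cry1
  target: Dbp
  sign: inhibition
  strength: 0.6
clamp_means:
  Bmal1: 3.05107810371062
  Rev_erba: 1.303411425727632
  Per2: 1.435127506045539
  Cry1: 1.971418165272234
  Dbp: 2.040472265632115
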