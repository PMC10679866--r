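# Light-step experiment at 5 uM bath ThT: dark equilibration, then the
# photosensitization rates are raised 10-fold at t = 120 s.
tht_ext: 5
tmrm_ext: 0.025
Km: 500
Kc: 50
n: 4
delta: 15
events:
- t: 120
  type: scale_kon
  value: 10
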