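# Example synthetic rest-tremor scenario: y-dominant 4 Hz oscillation with
# a weaker x component, pink accelerometer noise and a small DC offset.
duration_s: 60.0
fs: 208.03
envelope:
  'y': 0.6
  x: 0.2
freq: 4
dc_offset:
- 0.02
- -0.98
- 0.05
noise_kind: pink
noise_scale: 0.1
phase0: 0.0
envelope_method: linear
seed: 7
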