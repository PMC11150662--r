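command: frobnicate
args:
- frobnicate
- --seed
- '1'
seed: 1.0
w1: 1.0
w2: 1.0

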