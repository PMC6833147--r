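name: toy_rich_synthetic
description: Synthetic stand-in for a rich (YPD-like) medium for the toy fixtures;
  extend with rescue exchanges as needed
bounds:
  EX_A:
  - -10.0
  - 1000.0
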