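name: toy_minimal
description: Single carbon substrate A, open secretion; the defined minimal medium
  of the toy world
bounds:
  EX_A:
  - -10.0
  - 1000.0
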