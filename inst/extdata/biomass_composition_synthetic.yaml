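# Synthetic biomass composition for the TOY-BIO fixture world (the five
# generic precursors P1..P5 stand in for amino acids, carbohydrate, RNA and
# DNA monomers). Mass fractions are yeast-like; residue masses are
# polymer-incorporated (g/mmol).
macro_fractions:
  protein: 0.45
  carbohydrate: 0.35
  rna: 0.12
  dna: 0.08
monomer_fractions:
  protein:
    P1_c: 0.6
    P2_c: 0.4
  carbohydrate:
    P3_c: 1.0
  rna:
    P4_c: 1.0
  dna:
    P5_c: 1.0
monomer_masses:
  P1_c: 0.110
  P2_c: 0.130
  P3_c: 0.162
  P4_c: 0.320
  P5_c: 0.310
gam: 0
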