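# Default cell-cycle phase gene lists (canonical murine cycle genes).
# Editable: supply your own file of the same shape to scoreCellCycle().
G1S:
  - Mcm2
  - Mcm5
  - Mcm6
  - Pcna
  - Ccne1
  - Ccne2
  - Cdc6
  - Rrm1
  - Rrm2
  - Slbp
  - Gins2
  - Uhrf1
G2M:
  - Ccnb1
  - Ccnb2
  - Ccna2
  - Top2a
  - Bub1
  - Bub1b
  - Cdk1
  - Plk1
  - Aurka
  - Aurkb
  - Birc5
  - Ube2c
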