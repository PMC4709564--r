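# Default domain map for a tapasin-MHC I complex on author/PDB numbering.
# alpha1/alpha2/alpha3 boundaries are APPROXIMATE (conventional MHC I fold
# boundaries) and user-overridable; TN/TC follow the tapasin construct split
# at residue 270. Chains: A = MHC I heavy chain, B = beta-2 microglobulin,
# C = antigen peptide, D = tapasin.
alpha1:
- chain: A
  from: 1
  to: 90
alpha2:
- chain: A
  from: 91
  to: 182
alpha3:
- chain: A
  from: 183
  to: 276
b2m:
- chain: B
  from: 1
  to: 99
Ag:
- chain: C
  from: 1
  to: 9
TN:
- chain: D
  from: 1
  to: 269
TC:
- chain: D
  from: 270
  to: 381
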