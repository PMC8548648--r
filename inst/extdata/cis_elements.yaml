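# Editable cis-regulatory element dictionary: name -> IUPAC consensus.
# Consensus strings follow the style of plant promoter-element catalogs;
# matching is exact-consensus on both strands.
elements:
  TATA-box: TATAAA
  CAAT-box: CCAAT
  ABRE: ACGTGGC
  G-box: CACGTG
  GATA-motif: WGATAR
  MRE: AACCTAA
  RY-element: CATGCATG
  AE-box: AGAAACAA
  AACA-motif: AACAAAC
  GCN4-motif: TGAGTCA
  BoxII: GGTTAA
  LTRE: CCGAAA
  TC-rich: ATTTTCTTCA
  MBS: CAACTG
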