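# Editable marker configuration for corrinoid ecological-role classification.
# Identifiers are KEGG KOs or Pfam accessions. The Class II (corrinoid-
# dependent) ribonucleotide reductase must be detected via PF08471; K00525
# conflates Class I and Class II and is deliberately excluded everywhere.
biosynthesis:
  - K06042   # cbiC / cobH
  - K05936   # cbiF / cobM
  - K03394   # cbiL / cobI
dependent:
  methionine_synthase: [K00548]            # metH
  methylmalonyl_coa_mutase: [K01847, K01848, K01849]
  epoxyqueuosine_reductase: [K18979]       # queG
  ribonucleotide_reductase: [PF08471]      # Class II RNR
  corrinoid_methyltransferase: [K00577, K00584]  # mtrA, mtrH (unpaired)
independent:
  methionine_synthase: [K00549]            # metE
  methylmalonyl_coa_mutase: [K01659, K03417, K01720]  # methylcitrate pathway
  epoxyqueuosine_reductase: [K25284]       # queH
  ribonucleotide_reductase: [K00526, K21636]  # Class I beta, Class III
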