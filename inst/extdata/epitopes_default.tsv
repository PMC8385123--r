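# Example immune-epitope list for exact-containment mapping.
# Provenance of each entry is given in source_id:
#   - IEDB/omega-5-gliadin: wheat-dependent exercise-induced anaphylaxis
#     epitope QILQQQLIPC.
#   - DQ2.5-*: coeliac HLA-DQ2.5 T-cell 9-mer cores in Sollid nomenclature
#     (native, non-deamidated Q forms; literature defaults).
#   - R5/G12: core motifs recognized by the commercial ELISA monoclonal
#     antibodies (literature defaults).
#   - synthetic-scenario*: marker motifs used by the packaged simulation
#     scenario for the baker's-asthma and wheat-allergy categories; the
#     cross-reactive ones are listed under both categories. They are NOT
#     literature epitopes.
sequence	category	source_id
QILQQQLIPC	WDEIA	IEDB/omega-5-gliadin
PFPQPQLPY	CD_HLA_DQ	DQ2.5-glia-alpha1a
PYPQPQLPY	CD_HLA_DQ	DQ2.5-glia-alpha1b
PQPQLPYPQ	CD_HLA_DQ	DQ2.5-glia-alpha2
PQQSFPQQQ	CD_HLA_DQ	DQ2.5-glia-gamma1-like
QQPQQPYPQ	CD_HLA_DQ	DQ2.5-glia-gamma-like
PFPQPQQPF	CD_HLA_DQ	DQ2.5-glia-omega-like
CYPGQAFQVP	BA	synthetic-scenario
QCGALYSMLD	BA	synthetic-scenario
QPGQGQQGYYPTS	WA	synthetic-scenario
GQQPGQGQPGYYP	WA	synthetic-scenario
YCCQQLAQFPGQ	BA	synthetic-scenario-crossreactive
GVCCGQLSSMLP	BA	synthetic-scenario-crossreactive
YCCQQLAQFPGQ	WA	synthetic-scenario-crossreactive
GVCCGQLSSMLP	WA	synthetic-scenario-crossreactive
QQPFP	R5	R5-mAb-pentapeptide
QPQLPY	G12	G12-mAb-hexapeptide
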