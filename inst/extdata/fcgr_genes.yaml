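reference_fasta: fcgr_refs.fasta
genes:
- gene_id: FCGR1
  chromosome: chr1
  strand: '-'
  orf_start: 1
  signal_peptide_len: 17
  contact_source: 4W40+4ZNE
  contact_residues:
  - 85
  - 86
  - 87
  - 88
  - 109
  - 110
  - 111
  - 113
  - 114
  - 115
  - 116
  - 117
  - 119
  - 124
  - 125
  - 126
  - 127
  - 128
  - 129
  - 131
  - 132
  - 155
  - 156
  - 157
  - 158
  - 159
  exons:
  - label: '1'
    tstart: 1
    tend: 30
    gstart: 101380170
    gend: 101380199
  - label: '2'
    tstart: 31
    tend: 59
    gstart: 101379541
    gend: 101379569
  - label: '3'
    tstart: 60
    tend: 290
    gstart: 101378768
    gend: 101378998
  - label: '4'
    tstart: 291
    tend: 560
    gstart: 101374425
    gend: 101374694
  - label: '5'
    tstart: 561
    tend: 900
    gstart: 101372839
    gend: 101373178
  - label: '6'
    tstart: 901
    tend: 1125
    gstart: 101370875
    gend: 101371099
  domains:
  - start: -17
    end: -1
    label: signal
  - start: 1
    end: 82
    label: extracellular-D1
  - start: 83
    end: 172
    label: extracellular-D2
  - start: 173
    end: 292
    label: extracellular-other
  - start: 293
    end: 313
    label: transmembrane
  - start: 314
    end: 357
    label: cytoplasmic
  isoforms:
  - id: FCGR1_NM_001257304.2
    protein_id: NP_001244233.1
    edits: []
- gene_id: FCGR2A
  chromosome: chr1
  strand: '-'
  orf_start: 1
  signal_peptide_len: 35
  contact_source: 3RY6
  contact_residues:
  - 86
  - 87
  - 110
  - 114
  - 116
  - 117
  - 125
  - 126
  - 127
  - 129
  - 131
  - 155
  - 156
  - 157
  exons:
  - label: '1'
    tstart: 1
    tend: 55
    gstart: 89433945
    gend: 89433999
  - label: '2'
    tstart: 56
    tend: 105
    gstart: 89432895
    gend: 89432944
  - label: '3'
    tstart: 106
    tend: 300
    gstart: 89431290
    gend: 89431484
  - label: '4'
    tstart: 301
    tend: 723
    gstart: 89427065
    gend: 89427487
  - label: '5'
    tstart: 724
    tend: 810
    gstart: 89425190
    gend: 89425276
  - label: '6'
    tstart: 811
    tend: 850
    gstart: 89423150
    gend: 89423189
  - label: '7'
    tstart: 851
    tend: 933
    gstart: 89419220
    gend: 89419302
  domains:
  - start: -35
    end: -1
    label: signal
  - start: 1
    end: 80
    label: extracellular-D1
  - start: 81
    end: 172
    label: extracellular-D2
  - start: 173
    end: 216
    label: extracellular-other
  - start: 217
    end: 240
    label: transmembrane
  - start: 241
    end: 275
    label: cytoplasmic
  isoforms:
  - id: FCGR2A_NM_001257300.1
    protein_id: NP_001244229.1
    edits: []
  - id: FCGR2A_XM_015113136.2
    protein_id: XP_014968622.2
    edits:
    - type: residue_del
      residue: 36
  - id: FCGR2A_XM_028846297.1
    protein_id: XP_028702130.1
    edits:
    - type: splice5_ext
      label: '5'
      nt: 15
  - id: FCGR2A_XM_028846295.1
    protein_id: XP_028702128.1
    edits:
    - type: residue_del
      residue: 36
    - type: splice5_ext
      label: '5'
      nt: 15
  ext5_seqs:
    '5': GGTTCCGCTCAAGAA
- gene_id: FCGR2B
  chromosome: chr1
  strand: '-'
  orf_start: 1
  signal_peptide_len: 45
  contact_source: 3WJJ
  contact_residues:
  - 85
  - 86
  - 87
  - 110
  - 113
  - 117
  - 119
  - 126
  - 127
  - 128
  - 129
  - 130
  - 131
  - 157
  - 158
  - 159
  - 160
  exons:
  - label: '1'
    tstart: 1
    tend: 55
    gstart: 89333945
    gend: 89333999
  - label: '2'
    tstart: 56
    tend: 105
    gstart: 89332895
    gend: 89332944
  - label: '3'
    tstart: 106
    tend: 300
    gstart: 89332200
    gend: 89332394
  - label: '4'
    tstart: 301
    tend: 650
    gstart: 89331001
    gend: 89331350
  - label: '5'
    tstart: 651
    tend: 820
    gstart: 89329380
    gend: 89329549
  - label: '7'
    tstart: 821
    tend: 903
    gstart: 89326799
    gend: 89326881
  - label: '8'
    tstart: 904
    tend: 933
    gstart: 89324867
    gend: 89324896
  domains:
  - start: -45
    end: -1
    label: signal
  - start: 1
    end: 80
    label: extracellular-D1
  - start: 81
    end: 172
    label: extracellular-D2
  - start: 173
    end: 237
    label: extracellular-other
  - start: 238
    end: 256
    label: transmembrane
  - start: 257
    end: 265
    label: cytoplasmic
  isoforms:
  - id: FCGR2B_XM_015113204.2
    protein_id: XP_014968690.1
    edits: []
  - id: FCGR2B_XM_015113196.2
    protein_id: XP_014968682.1
    edits:
    - type: exon_include
      label: '6'
  - id: FCGR2B_NM_001257302.1
    protein_id: NP_001244231.1
    edits:
    - type: residue_ins
      residue: 20
      aa: A
  - id: FCGR2B_NM_001271648.2
    protein_id: NP_001258577.2
    edits:
    - type: exon_include
      label: '6'
    - type: residue_ins
      residue: 20
      aa: A
  alt_exons:
  - label: '6'
    insert_after: 903
    seq: GAAGATCACACCTATTCCGAGGTCCAGTTCAGACCAGTGCTGCCTTCCATGGTGAAG
    gstart: 89326200
    gend: 89326256
- gene_id: FCGR3
  chromosome: chr1
  strand: +
  orf_start: 54
  signal_peptide_len: 54
  contact_source: 7KCZ
  contact_residues: 158
  exons:
  - label: '1'
    tstart: 1
    tend: 173
    gstart: 89379948
    gend: 89380120
  - label: '2'
    tstart: 174
    tend: 223
    gstart: 89383121
    gend: 89383170
  - label: '3'
    tstart: 224
    tend: 483
    gstart: 89387012
    gend: 89387271
  - label: '4'
    tstart: 484
    tend: 703
    gstart: 89390624
    gend: 89390843
  - label: '5'
    tstart: 704
    tend: 896
    gstart: 89392640
    gend: 89392832
  domains:
  - start: -54
    end: -1
    label: signal
  - start: 1
    end: 80
    label: extracellular-D1
  - start: 81
    end: 172
    label: extracellular-D2
  - start: 173
    end: 192
    label: extracellular-other
  - start: 193
    end: 210
    label: transmembrane
  - start: 211
    end: 226
    label: cytoplasmic
  isoforms:
  - id: FCGR3_NM_001271657.1
    protein_id: NP_001258586.1
    edits: []
  - id: FCGR3_XM_015113175.2
    protein_id: XP_014968661.2
    edits:
    - type: residue_ins
      residue: 10
      aa: A
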