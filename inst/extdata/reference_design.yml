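barcodes:
  S1:
    sequence: ACGTACGT
    species: human
  S2:
    sequence: TGCATGCA
    species: mouse
  S3:
    sequence: AAGGTTCC
    species: human
  S4:
    sequence: GGTTCCAA
    species: mouse
umi1_len: 8
umi2_len: 8
anchor5: GCGATCGAGGAC
anchor3: CTGTCTCTTATA
cell_barcode_len: 16
tolerances:
  hash: 1
  cell: 1
  anchor: 2
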