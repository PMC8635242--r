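Pro-Ins:
  name: Pro-Ins
  type: indel
  forward:
    name: Pro-Ins-F
    seq: GGGTTGTGCCTAAATAGCA
  reverses:
  - name: Pro-Ins-R
    seq: AAGGAAGAGCGTGGTTCA
  enzyme: ~
  classes:
  - class: '623'
    fragments:
    - 623
    haplotypes:
    - H1
    - H2
  - class: insertion-present
    fragments:
    - 775
    - 777
    haplotypes:
    - H3
    - H4
    - H5
H2-Ins:
  name: H2-Ins
  type: indel
  forward:
    name: H2-Ins-F
    seq: GCGGGAGTAATGTTATCGG
  reverses:
  - name: H2-Ins-R/H1
    seq: CGATTAGCTCCACCAACCCT
    allele_tag: H1-type
  - name: H2-Ins-R/H2
    seq: GTCGTATCTTGGGAGAGGAG
    allele_tag: H2-specific
  enzyme: ~
  classes:
  - class: '364'
    fragments:
    - 364
    haplotypes:
    - H1
    - H3
    - H4
    - H5
  - class: '565'
    fragments:
    - 565
    haplotypes: H2
H3-MboII:
  name: H3-MboII
  type: CAPS
  forward:
    name: H3-MboII-F
    seq: TATGGTGGCTAAGCAGGTG
  reverses:
  - name: H3-MboII-R
    seq: CAGTGAGTTCGGTAAGTTGC
  enzyme:
    name: MboII
    recognition: GAAGA
    cut_offset: 8
    palindromic: no
  classes:
  - class: three-fragment
    fragments:
    - - 125
      - 119
      - 52
    haplotypes: H3
  - class: two-fragment
    fragments:
    - - 244
      - 52
    haplotypes:
    - H1
    - H2
    - H4
    - H5
H4-NlaIII:
  name: H4-NlaIII
  type: CAPS
  forward:
    name: H4-NlaIII-F
    seq: AAAGCGCATAAGTTATAACACAAAAT
  reverses:
  - name: H4-NlaIII-R
    seq: GAATGTAACCCTATCATGTCTGTCA
  enzyme:
    name: NlaIII
    recognition: CATG
    cut_offset: 0
    palindromic: yes
  classes:
  - class: four-fragment
    fragments:
    - - 111
      - 87
      - 42
      - 22
    haplotypes: H4
  - class: two-fragment
    fragments:
    - - 133
      - 129
    haplotypes:
    - H1
    - H2
  - class: three-fragment
    fragments:
    - - 133
      - 87
      - 42
    haplotypes:
    - H3
    - H5
H5-Del:
  name: H5-Del
  type: indel
  forward:
    name: H5-Del-F
    seq: CTGTCCATCACGGCTTTCC
  reverses:
  - name: H5-Del-R
    seq: CTATAGTAGGTCCACCTGAGAA
  enzyme: ~
  classes:
  - class: '210'
    fragments:
    - 210
    haplotypes: H5
  - class: '214'
    fragments:
    - 214
    haplotypes:
    - H1
    - H2
    - H3
    - H4
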