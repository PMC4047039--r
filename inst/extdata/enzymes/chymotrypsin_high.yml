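name: chymotrypsin_high
# High-specificity chymotrypsin: aromatic P1 (F/Y/W), no cleavage before P,
# and W-M / W-P bonds are resistant.
rules:
- kind: permit
  conditions:
    "-1": "FYW"
    "+1": "ACDEFGHIKLMNQRSTVWY"
- kind: exception_block
  conditions:
    "-1": "W"
    "+1": "MP"
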