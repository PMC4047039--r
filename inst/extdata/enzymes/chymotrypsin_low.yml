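name: chymotrypsin_low
# Low-specificity chymotrypsin: adds L/M/H at P1 to the aromatic set, with
# the documented resistant pairs (W-M/P, M-Y, H-D/M/P/W).
rules:
- kind: permit
  conditions:
    "-1": "FYW"
    "+1": "ACDEFGHIKLMNQRSTVWY"
- kind: permit
  conditions:
    "-1": "LMH"
    "+1": "ACDEFGHIKLMNQRSTVWY"
- kind: exception_block
  conditions:
    "-1": "W"
    "+1": "MP"
- kind: exception_block
  conditions:
    "-1": "M"
    "+1": "Y"
- kind: exception_block
  conditions:
    "-1": "H"
    "+1": "DMPW"
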