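name: pepsin_ph1.3
# Pepsin at fasted gastric pH (~1.3): hydrophobic F/L at P1, disfavoured by
# proline at P1' or P2.  A compact stand-in for Keil's statistical matrix;
# drop in a fuller transcription here without code changes.
rules:
- kind: permit
  conditions:
    "-1": "FL"
- kind: exception_block
  conditions:
    "+1": "P"
- kind: exception_block
  conditions:
    "-2": "P"
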