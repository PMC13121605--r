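T_cells:
  type: and
  children:
  - type: threshold
    marker: CD3
    op: '>'
    value: 0.7
  - type: not
    children:
    - type: threshold
      marker: CD19
      op: '>'
      value: 0.5
  name: T_cells
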