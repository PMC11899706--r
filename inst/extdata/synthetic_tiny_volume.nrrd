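NRRD0004
# synthetic test fixture (hand-written ascii encoding)
type: unsigned char
dimension: 3
sizes: 4 3 2
spacings: 0.05 0.06 0.1
encoding: ascii

241 160 175 229 148 198 213 57 14 76 72 223 233 1 127 210 33 204 30 119 209 77 87 71
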