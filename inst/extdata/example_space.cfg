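# example chemical-space definition: one atom type per line (element: valence),
# plus the total atom-count window
C: 4
H: 1
F: 1
natoms: [2, 8]
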