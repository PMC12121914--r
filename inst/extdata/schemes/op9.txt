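# 9-group reduced amino-acid alphabet.
# Reconstructed as a nested coarsening of the canonical 11-group
# partition (I/V+L/M merged; H/S+T merged); not taken verbatim from any
# published table.
G: G
I: IVLM
F: FYW
A: A
E: EQRK
P: P
N: ND
H: HST
V: C
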