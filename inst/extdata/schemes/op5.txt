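# 5-group reduced amino-acid alphabet.
# Reconstructed as a nested coarsening of the canonical 11-group
# partition along physicochemical similarity (small / aliphatic+sulfur /
# aromatic / charged+amide / polar); not taken verbatim from any
# published table.
G: GAP
I: IVLMC
F: FYW
E: EQRK
N: NDHST
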