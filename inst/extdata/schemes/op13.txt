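# 13-group reduced amino-acid alphabet.
# Reconstructed as a refinement of the canonical 11-group partition
# (aromatics split F/Y vs W; charged split E/Q vs R/K); not taken
# verbatim from any published table.
G: G
I: IV
F: FY
W: W
A: A
L: LM
E: EQ
R: RK
P: P
N: ND
H: HS
T: T
V: C
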