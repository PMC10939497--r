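# SYNTHETIC stand-in hydrophobic-strength scale for the 1BPA force field.
# eps = 0.05 + 0.90 * (KD + 4.5) / 9 (min-max normalized Kyte-Doolittle
# hydropathy mapped into (0,1)); charged residues (D, E, K, R) +0.10,
# mirroring the documented slight increase of charged-residue strengths.
# Replace with a measured scale via read_hydropathy(path) if available.
residue	eps
A	0.68
R	0.15
N	0.15
D	0.25
C	0.75
Q	0.15
E	0.25
G	0.46
H	0.18
I	0.95
L	0.88
K	0.21
M	0.69
F	0.78
P	0.34
S	0.42
T	0.43
W	0.41
Y	0.37
V	0.92
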