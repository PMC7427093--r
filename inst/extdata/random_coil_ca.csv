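# Random-coil 13C-alpha chemical shifts (ppm), referenced to DSS.
# Values from Wishart, Bigam, Holm, Hodges & Sykes (1995) J Biomol NMR 5:67-81
# (peptide random-coil set, no neighbour-sequence corrections applied).
residue,shift_ca_ppm
A,52.5
C,58.2
D,54.2
E,56.6
F,57.7
G,45.1
H,55.0
I,61.1
K,56.2
L,55.1
M,55.4
N,52.8
P,63.3
Q,56.6
R,56.0
S,58.3
T,61.8
V,62.2
W,57.5
Y,57.9
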