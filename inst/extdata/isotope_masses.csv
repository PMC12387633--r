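# Most-abundant-isotope atomic masses, CODATA/AME2020, version 1.0
element,mass
C,12.0
H,1.00782503207
N,14.0030740048
O,15.9949146196
Na,22.9897692809
K,38.96370668
S,31.97207100
P,30.97376163
Si,27.97692653
Cl,34.96885268
F,18.99840322
e,0.00054857990946
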