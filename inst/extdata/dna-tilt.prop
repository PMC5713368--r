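# Dinucleotide tilt step parameter (representative published-lineage values).
#name: dna.tilt
#seqtype: DNA
#tuple: 2
AA -1.4
AC -0.1
AG -1.7
AT 0.0
CA 0.5
CC -0.1
CG 0.0
CT 1.7
GA -1.5
GC 0.0
GG 0.1
GT 0.1
TA 0.0
TC 1.5
TG -0.5
TT 1.4
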