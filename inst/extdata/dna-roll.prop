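# Dinucleotide roll step parameter (representative published-lineage values).
#name: dna.roll
#seqtype: DNA
#tuple: 2
AA 0.7
AC 0.7
AG 4.5
AT 1.1
CA 4.7
CC 3.6
CG 5.4
CT 4.5
GA 1.9
GC 0.3
GG 3.6
GT 0.7
TA 3.3
TC 1.9
TG 4.7
TT 0.7
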