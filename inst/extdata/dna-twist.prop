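# Dinucleotide twist step parameter (representative published-lineage values).
#name: dna.twist
#seqtype: DNA
#tuple: 2
AA 38.90
AC 31.12
AG 32.29
AT 33.28
CA 37.43
CC 32.06
CG 36.94
CT 32.29
GA 39.33
GC 40.03
GG 32.06
GT 31.12
TA 40.93
TC 39.33
TG 37.43
TT 38.90
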