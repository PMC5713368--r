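# Dinucleotide rise step parameter (representative published-lineage values).
#name: dna.rise
#seqtype: DNA
#tuple: 2
AA 3.27
AC 3.36
AG 3.34
AT 3.31
CA 3.33
CC 3.42
CG 3.39
CT 3.34
GA 3.37
GC 3.40
GG 3.42
GT 3.36
TA 3.42
TC 3.37
TG 3.33
TT 3.27
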