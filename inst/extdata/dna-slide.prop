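# Dinucleotide slide step parameter (representative published-lineage values).
#name: dna.slide
#seqtype: DNA
#tuple: 2
AA -0.08
AC -0.58
AG -0.25
AT -0.59
CA 0.53
CC -0.22
CG 0.41
CT -0.25
GA 0.09
GC -0.38
GG -0.22
GT -0.58
TA 0.05
TC 0.09
TG 0.53
TT -0.08
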