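# Dinucleotide shift step parameter (representative published-lineage values).
#name: dna.shift
#seqtype: DNA
#tuple: 2
AA -0.03
AC 0.13
AG 0.09
AT 0.00
CA 0.09
CC 0.05
CG 0.00
CT -0.09
GA -0.28
GC 0.00
GG -0.05
GT -0.13
TA 0.00
TC 0.28
TG -0.09
TT 0.03
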