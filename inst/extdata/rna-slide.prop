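# Dinucleotide slide step parameter (representative published-lineage values).
#name: rna.slide
#seqtype: RNA
#tuple: 2
AA -1.27
AC -1.43
AG -1.50
AU -1.36
CA -1.46
CC -1.78
CG -1.89
CU -1.50
GA -1.70
GC -1.39
GG -1.78
GU -1.43
UA -1.45
UC -1.70
UG -1.46
UU -1.27
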