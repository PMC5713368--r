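# Dinucleotide shift step parameter (representative published-lineage values).
#name: rna.shift
#seqtype: RNA
#tuple: 2
AA -0.08
AC 0.23
AG -0.04
AU -0.06
CA 0.11
CC -0.01
CG 0.30
CU -0.04
GA 0.07
GC 0.07
GG -0.01
GU 0.23
UA -0.02
UC 0.07
UG 0.11
UU -0.08
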