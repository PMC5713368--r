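# Dinucleotide twist step parameter (representative published-lineage values).
#name: rna.twist
#seqtype: RNA
#tuple: 2
AA 31.3
AC 32.0
AG 30.5
AU 33.1
CA 32.7
CC 33.2
CG 27.8
CU 30.5
GA 35.0
GC 34.3
GG 33.2
GU 32.0
UA 36.3
UC 35.0
UG 32.7
UU 31.3
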