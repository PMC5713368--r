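# Dinucleotide rise step parameter (representative published-lineage values).
#name: rna.rise
#seqtype: RNA
#tuple: 2
AA 3.18
AC 3.24
AG 3.30
AU 3.24
CA 3.09
CC 3.32
CG 3.30
CU 3.30
GA 3.38
GC 3.22
GG 3.32
GU 3.24
UA 3.26
UC 3.38
UG 3.09
UU 3.18
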