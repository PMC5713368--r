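# Dinucleotide roll step parameter (representative published-lineage values).
#name: rna.roll
#seqtype: RNA
#tuple: 2
AA 7.0
AC 4.8
AG 8.5
AU 7.1
CA 9.9
CC 8.7
CG 12.1
CU 8.5
GA 9.4
GC 6.1
GG 8.7
GU 4.8
UA 10.7
UC 9.4
UG 9.9
UU 7.0
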