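# Dinucleotide tilt step parameter (representative published-lineage values).
#name: rna.tilt
#seqtype: RNA
#tuple: 2
AA -0.8
AC 0.8
AG 0.5
AU 1.1
CA 1.0
CC 0.3
CG -0.1
CU 0.5
GA 1.3
GC 0.0
GG 0.3
GU 0.8
UA -0.4
UC 1.3
UG 1.0
UU -0.8
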