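# SYNTHETIC trinucleotide scale: a constructed placeholder so the
# trinucleotide autocorrelation modes are runnable out of the box.
# Substitute a published trinucleotide scale via a property file
# for real analyses.
#name: dna3.syntha
#seqtype: DNA
#tuple: 3
AAA 2.918
AAC 4.057
AAG 4.783
AAT 4.997
ACA 4.67
ACC 3.846
ACG 2.637
ACT 1.206
AGA -0.252
AGC -1.541
AGG -2.486
AGT -2.96
ATA -2.897
ATC -2.307
ATG -1.269
ATT 0.076
CAA 1.546
CAC 2.942
CAG 4.075
CAT 4.792
CCA 4.996
CCC 4.659
CCG 3.827
CCT 2.612
CGA 1.179
CGC -0.278
CGG -1.562
CGT -2.5
CTA -2.963
CTC -2.891
CTG -2.291
CTT -1.247
GAA 0.102
GAC 1.573
GAG 2.965
GAT 4.092
GCA 4.8
GCC 4.994
GCG 4.648
GCT 3.807
GGA 2.587
GGC 1.152
GGG -0.304
GGT -1.583
GTA -2.513
GTC -2.967
GTG -2.884
GTT -2.276
TAA -1.224
TAC 0.129
TAG 1.6
TAT 2.989
TCA 4.109
TCC 4.809
TCG 4.993
TCT 4.636
TGA 3.788
TGC 2.562
TGG 1.125
TGT -0.33
TTA -1.604
TTC -2.526
TTG -2.97
TTT -2.878
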