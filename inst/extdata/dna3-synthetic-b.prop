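# SYNTHETIC trinucleotide scale: a constructed placeholder so the
# trinucleotide autocorrelation modes are runnable out of the box.
# Substitute a published trinucleotide scale via a property file
# for real analyses.
#name: dna3.synthb
#seqtype: DNA
#tuple: 3
AAA 2.2
AAC 1.857
AAG 0.922
AAT -0.348
ACA -1.605
ACC -2.504
ACG -2.798
ACT -2.407
AGA -1.438
AGC -0.156
AGG 1.086
AGT 1.948
ATA 2.193
ATC 1.754
ATG 0.751
ATT -0.54
CAA -1.765
CAC -2.588
CAG -2.783
CAT -2.297
CCA -1.263
CCC 0.035
CCG 1.242
CCT 2.025
CGA 2.171
CGC 1.638
CGG 0.574
CGT -0.73
CTA -1.916
CTC -2.659
CTG -2.754
CTT -2.176
GAA -1.083
GAC 0.224
GAG 1.388
GAT 2.089
GCA 2.134
GCC 1.511
GCG 0.392
GCT -0.918
GGA -2.058
GGC -2.715
GGG -2.71
GGT -2.044
GTA -0.899
GTC 0.41
GTG 1.525
GTT 2.138
TAA 2.083
TAC 1.374
TAG 0.205
TAT -1.102
TCA -2.189
TCC -2.758
TCG -2.652
TCT -1.901
TGA -0.711
TGC 0.592
TGG 1.65
TGT 2.173
TTA 2.018
TTC 1.226
TTG 0.016
TTT -1.281
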