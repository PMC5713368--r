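# seqvec

Machine-learning models need fixed-length numeric input, but biological
sequences come in every length. `seqvec` converts DNA, RNA, protein, or
user-defined-alphabet sequences from multi-line FASTA into fixed-length
descriptor vectors, for anyone building sequence classifiers or regressors:
site predictors, family classifiers, genome-scale feature matrices.

## The descriptors

For a sequence R₁R₂…R_L over an alphabet 𝒜, the package computes, among a
catalogue of 35 built-in modes:

- **k-mer composition** — f_u = count(u)/(L−k+1) over all |𝒜|^k tuples
  (optionally pooled onto canonical, reverse-complement-collapsed k-mers);
- **Type-1 (parallel) pseudo composition** (PseAAC / PseDNC / PseKNC):
  k-tuple frequencies extended with λ sequence-order factors
  θ_j = (1/(L−n+1−j)) Σᵢ Θ(Dᵢ, Dᵢ₊ⱼ), where
  Θ(a,b) = (1/Γ) Σ_k [H_k(a) − H_k(b)]² averages squared differences of Γ
  normalized physicochemical properties over n-tuples, all jointly
  normalized by Z = 1 + ω Σθ so the vector sums to 1;
- **Type-2 (series / amphiphilic) pseudo composition**: per-property
  product factors τ_{(j−1)Γ+v} = (1/(L−n+1−j)) Σᵢ P_v(Dᵢ)P_v(Dᵢ₊ⱼ)
  replacing θ;
- **autocorrelation families** — AC, CC, ACC, Moran, Geary, normalized
  Moreau–Broto over property profiles;
- **distance-pair frequencies** and **one-hot encoding**.

Property tables are z-scored with the population standard deviation, and
every pairwise Θ(a,b) and P_v(a)·P_v(b) is pre-computed once per mode
configuration, so per-sequence work is pure table lookup — verified
numerically identical to direct per-position evaluation.

Around the kernels sit a multi-line FASTA parser that auto-recognizes
UniProt, GenBank, EMBL, DDBJ and RefSeq header dialects, a user-selectable
skip-or-abort policy for data faults (non-standard letters, insufficient
length), a runtime extension system (a 23-function API for registering new
sequence types, properties, modes and CLI options), and libSVM/TSV/CSV
writers.

## Worked example

```r
library(seqvec)

recs <- list(sequence_record("demo1", "ACDEFGHIKLMNPQRSTVWY"),
             sequence_record("demo2", "AAAAACCCCCDDDDDEEEEE"))
res <- run_engine(recs, "PROT",
                  list(list(mode_id = "pseaac2",
                            params = list(lambda = 10, omega = 0.05))))
res
#> seqvec result: 2 descriptor vector(s) of dimension 40 (modes: pseaac2)
round(res$vectors$demo1[c(1, 2, 21, 22)], 4)
#> [1]  0.0547  0.0547 -0.0015  0.0047
writeLines(substr(write_svm(res)[1], 1, 58))
#> 0 1:0.0546626 2:0.0546626 3:0.0546626 4:0.0546626 5:0.0546
```

Each vector holds the 20 amino-acid frequencies (components 1–20) followed
by ω-weighted series-correlation factors for lags 1–10 over hydrophobicity
and hydrophilicity (components 21–40); all 40 components sum to 1.

The same run from a shell:

```sh
Rscript inst/cli/seqvec -f demo.fas -m pseaac2 -l 10 -w 0.05 -F svm
seqvec --list-modes     # the 35-mode catalogue
```

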