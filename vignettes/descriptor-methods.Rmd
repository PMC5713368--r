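---
title: "Sequence descriptors in seqvec: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence descriptors in seqvec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqvec)
```

## The problem

Statistical learning on biological sequences requires a map from a
variable-length string over an alphabet $\mathcal{A}$ to a vector in
$\mathbb{R}^D$ with $D$ fixed in advance. Pure composition vectors achieve
this but discard all sequence order; one-hot encodings keep order but tie
$D$ to a maximum length. The pseudo-composition family steers between the
two: composition plus a small number of *sequence-order correlation
factors* computed from physicochemical properties of residues or
nucleotide tuples. `seqvec` implements this family — together with
autocorrelation, distance-pair and one-hot descriptors — behind one
engine, one fault policy and one output layer.

## Sequence model

A sequence type is an ordered alphabet; the letter at position $u$ has
internal index $u-1$ (0-based internally, while formula subscripts below
are 1-based, the mathematical convention). Built-ins are DNA (A,C,G,T),
RNA (A,C,G,U) and PROT with the 20 standard amino-acid letters in
*alphabetical* order, so composition component $u$ always refers to the
$u$-th letter alphabetically. No canonical ordering exists in the
literature for protein composition components; alphabetical is the
reproducible choice, and any tool comparison must permute accordingly.

Input letters are folded to upper case by default because public-database
FASTA is mixed-case; a type-level flag disables folding for user alphabets
where case is semantic (e.g. lower-case letters as modified residues).
Whitespace and digits inside sequence lines are stripped, tolerating
column-formatted FASTA. DNA and RNA are distinct types with no automatic
U/T translation — a U under DNA is a data fault, because silent
translation hides upstream data errors.

Complement maps (needed by reverse-complement collapse) must be total on
the alphabet but need not be injective or involutive: an alphabet with a
methylated cytosine M naturally maps both C and M to G.

### Data faults

Real datasets downloaded from public databases contain records a
descriptor cannot process: non-standard letters (B, J, X, Z in proteins;
ambiguity codes in nucleotide data), sequences shorter than the requested
lag structure, and pathological denominators. These are *data faults*,
distinct from configuration errors. A user-chosen policy handles them:
`skip` excludes the record and emits exactly one report entry (id +
reason) on standard error, `abort` stops the whole run with a nonzero
exit. Parameter validation is deliberately dataset-independent, so one
short sequence can never abort a skip-policy run. Under skip, the
invariant `outputs + reports = inputs` holds for every dataset.

## Property tables and pre-computation

A property is a real-valued function on $n$-tuples of the alphabet
($n = 1$ for residues, 2 for dinucleotides, 3 for trinucleotides),
supplied as a plain-text file covering all $|\mathcal{A}|^n$ tuples.
Before use, raw values $H^0$ are standardized over all tuples:

$$H(a) = \frac{H^0(a) - \langle H^0 \rangle}{\sigma_{pop}(H^0)}$$

with the *population* (divide-by-$N$) standard deviation — the convention
of the classic pseudo-composition normalization, which this implementation
follows exactly; using the sample denominator would rescale every
correlation factor by $\frac{N-1}{N}$. A constant table has no information
and is rejected. Normalization is idempotent to within $10^{-9}$.

The quantities every correlation kernel consumes are pairwise: the
averaged squared difference
$\Theta(a,b) = \frac{1}{\Gamma}\sum_{k=1}^{\Gamma}[H_k(a)-H_k(b)]^2$
over a set of $\Gamma$ properties, and per-property products
$\Pi_v(a,b) = P_v(a)P_v(b)$. Both are pre-computed as
$|\mathcal{A}|^n \times |\mathcal{A}|^n$ matrices once per mode
configuration and cached per property set, so processing a sequence is
pure indexed lookup. The test suite and the reproduction script verify
that this fast path is numerically identical (to $10^{-12}$ and usually
exactly) to direct per-position re-evaluation. Tuple axes are ordered
lexicographically by alphabet index, row-major over positions
(dinucleotide index $= 4\,\mathrm{idx}(first) + \mathrm{idx}(second)$ for
DNA). $\Theta$ averages over properties by default, matching the classic
formulation; a flag selects the plain sum for user modes.

Bundled tables: the classic protein trio (hydrophobicity, hydrophilicity,
side-chain mass) and six dinucleotide step parameters each for DNA and
RNA, with representative published-lineage values. The two bundled
trinucleotide scales are *synthetic placeholders* (marked as such in
their files) so the trinucleotide modes run out of the box; real analyses
should supply published trinucleotide scales via `--props`. No
correctness test depends on any bundled value — all kernel tests use toy
tables generated in code.

## The descriptor kernels

With $D_i$ the $n$-tuple starting at position $i$, $N = L-n+1$ tuples and
$f_u$ the $k$-tuple frequencies (frequencies, not counts, everywhere —
required for the shared denominators below to take their stated form):

**Type-1 (parallel) pseudo composition.**
$\theta_j = \frac{1}{N-j}\sum_{i=1}^{N-j}\Theta(D_i, D_{i+j})$ for lags
$j = 1..\lambda$, then $Z = 1 + \omega\sum_j\theta_j$ and

$$x_u = f_u/Z \;(u \le |\mathcal{A}|^k), \qquad
  x_{|\mathcal{A}|^k+j} = \omega\,\theta_j/Z.$$

All components are nonnegative and sum to 1. $\lambda$ (default 1) sets
how many lag tiers of order information enter; it is bounded by $L-n$, so
short sequences fault. $\omega > 0$ (default 0.05) balances order factors
against composition: at $\omega \to 0$ the descriptor degenerates to the
composition, and large $\omega$ lets a few tiers dominate. At
$\lambda = 0$ the reduction to `kmer_composition` is *exact* (bitwise),
asserted in the tests.

**Type-2 (series / amphiphilic).** Per-property products replace the
averaged differences: $\tau_{(j-1)\Gamma+v} = \frac{1}{N-j}\sum_i
\Pi_v(D_i, D_{i+j})$, ordered lag-major then property-minor — for
proteins with $\Gamma = 2$ this reproduces the classic
$\tau_{2j-1}, \tau_{2j}$ hydrophobicity/hydrophilicity interleaving; for
$\Gamma > 2$ lag-major is the natural generalization and is this
package's declared ordering. $\tau$ can be negative, so
$Z = 1 + \omega\sum\tau$ can vanish; $|Z| < 10^{-12}$ is treated as a
per-record data fault (degenerate denominator), not an error, because it
is a property of one sequence under one parameterization.

**Autocorrelation family** (AC, CC, ACC, Moran, Geary, normalized
Moreau–Broto) over the property profile $P_v(D_i)$, centered at the
within-sequence mean, ordered lag-major. Zero-variance sequences
(homopolymers) make Moran and Geary 0/0; their components are *defined as
0* rather than faulting — homopolymers are legitimate input, and the
fault system is reserved for structural problems. Geary uses the
$N-1$ variance denominator, its textbook convention, hence requires
$N \ge 2$.

**Distance-pair** frequencies (distance-major, then ordered letter pair)
and **one-hot** (position-major, zero-padded to a mandatory
`target_length`; a longer sequence faults rather than being silently
truncated) complete the set.

The 35-mode catalogue (12 DNA, 8 RNA, 15 protein) wires these kernels to
default property sets and parameter schemas; `list_modes()` is the stable,
sorted contract. Every mode's output dimension is a function of its
parameters only, never of $L$.

## FASTA handling

The parser accepts multi-line records, LF/CRLF, missing trailing
newlines, and blank lines. Header dialects are recognized in a fixed
order — UniProt (`sp|ACC|ENTRY`), NCBI legacy `gi|N|db|ACC|`, ENA
(`ENA|ACC|...` → EMBL), modern RefSeq accessions (`XX_digits`), modern
GenBank/DDBJ accessions (1–2 letters + 5–6 digits) — first match wins.
GenBank and DDBJ accessions share a namespace and are both tagged
GENBANK; this is a documented limitation, not a bug. Identifiers must be
unique per file; when accession extraction collides across distinct
header lines, the affected records fall back to their full header text as
identifier, and only a collision surviving that fallback is a parse
error. The exact accession grammars are this package's contract — public
databases do not publish a single normative grammar.

## Extension system

Extensions are R source files evaluated against a fixed 23-function API:
registration (`register_seqtype`, `register_property`, `register_mode`,
`declare_option`), configuration (`get_option`, `set_output_format`),
per-sequence accessors valid only inside a compute rule
(`current_seq_id`, `current_sequence`, `current_indices`, `seq_length`,
`alphabet`, `alphabet_size`), property access (`get_property_raw`,
`get_property_normalized`, `property_value`), kernel helpers
(`kmer_counts`, `theta_parallel`, `tau_series`, `build_pair_tables`), and
output control (`emit_vector`, `set_label`, `skip_sequence`,
`log_message`). The API surface — not any particular scripting engine —
is the portable contract; a built-in mode re-expressed through it is
bit-identical to the built-in, which the tests assert on 100 random
sequences. Loading is transactional (a failing file registers nothing),
collisions with existing mode ids are load failures, and extensions may
re-bind a CLI flag's meaning with last-loaded-wins semantics and a logged
note. Loading an extension executes its code; no sandboxing is attempted.
Extensions load only from explicit `-d` flags, never implicitly from the
working directory.

## Output

All three writers (libSVM, TSV, CSV) print the same numbers: shortest
decimal form at 6 significant digits, no scientific notation below
$10^6$, so values round-trip at the printed precision and the format
choice cannot change results. The libSVM writer emits zero components by
default — sparse dropping would make column counts data-dependent —
with a `sparse` option for users who want compact files. Labels default
to 0; extensions can set per-record labels. Skip reports and the summary
count go to standard error, never into the data stream.

## What the synthetic generator emulates — and what it does not

`random_records()`/`random_fasta()` draw letters i.i.d. uniformly over
the alphabet and inject two realistic fault classes: out-of-alphabet
letters (as UniProt's B/J/X do) and truncated records. This exercises
every code path — encoding, fault policy, all kernels, writers — but
uniform i.i.d. sequences have no compositional bias, no long-range
structure and no homology, so passing tests certify *computational
correctness*, not predictive usefulness of any descriptor on real data.
Property toy tables are standard-normal draws, which decouples kernel
correctness from literature values.

Problem sizes in the shipped suite: 500 random sequences of length 5–50
for oracle equivalence against an independently coded naive double-loop
implementation (tolerance $10^{-12}$), 1000 random inputs for the
reduction/sum-to-one/nonnegativity invariants, 100 sequences for the
worked Type-2 configuration and the extension round trip. The two-letter
{A,B} alphabet is used for oracle work because it maximizes collision
coverage per CPU cycle without changing any code path.

## Known limitations

- No ambiguity-code expansion: N, R, Y are faults unless the user defines
  an alphabet containing them. No translation, whole-record
  reverse-complementation or ORF logic.
- FASTA only; no FASTQ, no compressed input.
- GenBank/DDBJ header tags are not distinguishable from the accession
  alone.
- Bundled property values are representative of the published lineage
  (and the trinucleotide scales are synthetic placeholders); analyses
  that depend on specific literature scales should load them explicitly.
- Descriptor modes requiring external databases (PSSM profiles, GO
  annotations, functional domains) are out of scope.
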