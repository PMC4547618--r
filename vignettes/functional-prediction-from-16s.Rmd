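---
title: "Predicting community gene content from 16S rRNA profiles: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting community gene content from 16S rRNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliko)
```

## The model

`ampliko` treats functional prediction as a linear pipeline over relative
abundance vectors. A community's 16S rRNA amplicon data, summarised as OTU
abundances `x` over marker reference sequences, is transformed into a
predicted relative KEGG Ortholog (KO) profile `k` in three steps:

1. `o = A x` — a sparse association matrix `A` (genomes × marker references)
   transfers OTU mass onto functionally annotated genomes;
2. `o'_g ∝ o_g / c_g` — division by each genome's 16S rRNA gene copy number
   `c_g`, undoing the amplicon over-representation of multi-copy genomes;
3. `k = Σ_g o'_g p_g` — a convex combination of the genomes' relative KO
   profiles `p_g`.

Each `p_g` row sums to 1, and `o'` is a probability vector, so `k` is
automatically a relative profile. The central assumption is taxonomic
conservation of gene content: a community member contributes approximately
the KO repertoire of its nearest sequenced relative. The method makes no
attempt to infer gene content for lineages without a close sequenced genome;
their abundance mass is *dropped and reported* instead of guessed. The
complementary coverage diagnostics (fraction of OTU mass mapped, optionally
multiplied by the upstream classified-read fraction) are therefore part of
the result, not an afterthought: a prediction using 5 % of the reads can
still correlate well with a shotgun profile while describing only a sliver
of the community's repertoire.

## The association matrix

`A` is built once per reference database by nearest-neighbour matching.
Every marker reference is globally aligned (Needleman–Wunsch, end-to-end)
against every genome 16S sequence; identity is the fraction of identical
columns in the optimal alignment.

Choices that were genuinely open, and how they were fixed:

* **Similarity measure.** Global-alignment identity with match +1,
  mismatch −1, gap −1 (linear gaps). Full-length identity is the standard
  similarity currency for rRNA sequences, and this parameterisation is
  exactly checkable against exhaustive alignment enumeration on short
  sequences, which the test suite does. The scoring triple is an argument,
  not a constant.
* **Co-optimal alignments.** Identity is only defined relative to one chosen
  alignment. Among score-optimal alignments the package picks the one
  maximising matches, then minimising columns — a deterministic,
  per-column-additive rule, so a single dynamic program finds it and results
  are reproducible across platforms.
* **Minimum identity.** Default 0.97, the conventional species-level 16S
  radius; a reference below threshold to every genome gets an all-zero
  column. Raising the threshold can only unmap references (tested as a
  monotonicity property).
* **Ties.** Exact-maximum neighbours (within 1e−12) split the column weight
  uniformly. Winner-take-all would be arbitrary among genomes the data
  cannot distinguish; the uniform split keeps every mapped column summing to
  exactly 1 (weights are rationals `1/|ties|`), which in turn makes the
  unmapped-mass bookkeeping exact.
* **Multiple 16S copies per genome.** A genome scores as the maximum
  identity over its copies, so within-genome rRNA divergence never penalises
  the genome.
* **Ambiguity codes.** `N` scores as a mismatch against everything,
  keeping reported identity a lower bound.

## Where normalization happens

Profiles carry absolute counts until a stage explicitly normalises.
Stage 1 drops unmapped mass and renormalises, reporting the dropped fraction
(`fraction_otus_unmapped`); stage 2 renormalises after copy-number division;
stage 3 needs no renormalisation. Only relative KO profiles are ever
evaluated downstream, which is why relative-after-each-stage is the adopted
convention; the alternative — carrying the unmapped deficit into the KO
profile — would silently deflate every KO dimension by a sample-dependent
factor. Numerical tolerances: a profile counts as normalised when its sum is
within 1e−9 of 1 (far above double rounding, far below any biological
signal); tie detection in the matrix builder uses 1e−12.

A missing copy number for an abundant organism is an error, not a silent
default of 1 — an invisible default would corrupt the correction; the
explicit `assume_copy_number_1` argument (CLI flag `--assume-copy-number-1`)
opts in deliberately.

## Evaluation protocol

Paired 16S/shotgun samples are compared by the Spearman correlation of their
relative KO profiles after *zero-dimension exclusion*: KO dimensions with no
mass in either profile are removed, since a huge shared-zero tail would
inflate rank agreement. Exclusion is applied per sample pair by default —
the stricter, self-contained reading — with `exclusion_scope = "dataset"`
pooling the retained set across samples as the documented alternative.
Spearman uses mid-ranks for ties (the standard definition); constant input
is an explicit error rather than `NA`. Method comparisons use the exact
two-sided sign test on per-sample coefficient differences: zeros dropped,
and with `k` positive among `n` nonzero differences,
`p = min(1, 2·min(P(X≤k), P(X≥k)))`, `X ~ Binomial(n, ½)`, computed from
exact binomial coefficient sums — no normal approximation, since paired
benchmark collections are typically small.

## The synthetic fixture generator

The generator emulates the structural relationship the method exploits: a
marker-reference database that is larger than, and noisily related to, the
set of annotated genomes. Per organism it draws a random 16S-like sequence,
derives its database reference by independent per-site substitutions, draws
a sparse KO annotation and a copy number; extra unrelated references model
database entries with no sequenced neighbour. Paired samples draw the 16S
side multinomially with probabilities proportional to
`mixing_weight × copy_number` — the copy-number bias is injected on purpose
so the correction stage is genuinely exercised — while the metagenome side
is the exact convex combination of KO rows, optionally perturbed by
multiplicative log-normal noise (`sdlog = noise_rate`), which is simple,
positive and rank-perturbing.

Defaults describe a small but realistic desk-scale universe: 10 organisms,
500 bp sequences (a typical amplicon region length), per-site mutation rate
0.01 (placing references at ~99 % identity, comfortably above the 0.97
threshold), 20 KOs per organism from a 100-KO pool, copy numbers 1–5 (the
bulk of the observed bacterial range), 10⁴ reads per sample. Mutation is
substitution-only so the engineered identities stay analytically predictable;
indels, chimeras, primer bias and rRNA secondary structure are *not*
modelled. Consequently, passing tests demonstrate the correctness of the
pipeline's arithmetic and its behaviour under sampling and noise — they do
not certify accuracy on real communities, which is governed by how well
real genomes cover the habitat.

All generation is seed-deterministic and restores the caller's RNG state;
identical specs serialize byte-identically.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run everything at the generator's
default scale (10-organism databases, 10 fixture seeds, 10⁴-read samples,
200 enumeration-checked alignments up to length 8, 500 oracle-checked
correlation vectors up to n = 50) — sizes chosen so the full reference
build, including the quadratic-time alignments, completes in seconds while
every stage still has non-trivial structure. Degenerate inputs are explicit
errors with named offenders: empty or all-zero profiles, sequences outside
`{A,C,G,T,U,N}`, all-zero KO annotations, constant correlation input,
all-zero sign-test differences, and references whose entire mass is
unmappable ("no OTU mapped").

## Known limitations

* Gene content is transferred wholesale from the nearest genome; strain-level
  gene gain/loss is invisible.
* The unmapped fraction is the only honesty mechanism: two samples with very
  different coverages should not have their predicted profiles compared
  naively.
* KO-to-pathway aggregation, rarefaction and taxonomic rollups are out of
  scope; outputs are flat KO vectors.
* The QIIME reader supports the classic plain-text OTU table only (no
  BIOM/HDF5), and the assignment-export reader accepts the two documented
  delimiter dialects.
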