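---
title: "Organelle genome variation, diagnostic markers and parsimony networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organelle genome variation, diagnostic markers and parsimony networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larchvar)
```

`larchvar` analyses variation among near-identical circular organelle
genomes — chloroplast genomes assembled per individual and aligned into a
whole-genome multiple alignment, and mitochondrial SNP matrices scored
from short de-novo contigs. This vignette is the package's account of the
underlying methods: what each stage assumes, which parameters matter, and
where the genuinely open design choices were settled.

## The data model

The central container is a `genome_alignment`: equal-length rows over
`A,C,G,T,N,-`, one per individual, with a designated reference row. All
user-facing coordinates are 1-based and closed; positions are reported
both as alignment columns and as ungapped reference positions
(`map_column_to_reference`). Circularity is carried as a flag only:
alignment columns are linear, and the synthetic generator never plants an
event spanning the origin — a documented limitation, acceptable because
assemblers conventionally linearise circular genomes at a fixed origin.
IUPAC ambiguity codes other than `N` are demoted to `N` on input (with a
warning): the upstream remedy for ambiguity is re-sequencing, which is out
of scope, so the scanner treats any residual uncertainty as missing.

## Variant scanning

The scanner partitions polymorphic columns into disjoint events with
classification precedence Inversion > HomopolymerDiff > InDel > SNP:

- **SNP** — a single gap-free column with ≥ 2 distinct bases among
  non-`N` entries. Multi-allelic columns count as *one* site; substitution
  classes are then assigned per minority allele against the majority
  allele, and the event-level class is left undefined. At a 50/50
  frequency tie the lexicographically smaller base is called minor, which
  makes singleton and minority bookkeeping deterministic.
- **InDel** — one *maximal run* of columns in which at least one row is
  gapped counts as one event, not one event per column; this matches how
  events are counted in comparative chloroplast work, where a 4-nt
  deletion is one InDel.
- **HomopolymerDiff** — an InDel whose gapped/inserted bases are all one
  base `X` and whose surrounding reference mononucleotide run (counted
  through and around the event) reaches `homopolymer_min_run` (default 4,
  configurable since no published threshold exists). Sequencing and
  assembly of mononucleotide runs is error-prone, so these length
  differences are reported apart from ordinary InDels and excluded from
  marker design.
- **Inversion** — a maximal run of ≥ `inversion_min_span` (default 2)
  consecutive substitution columns whose two observed allele strings are
  reverse complements of each other, emitted as one event and excluded
  from the SNP count. We classify on reverse-complement alleles alone and
  do not require flanking inverted-repeat arms to be annotated: hairpin
  flips are the mechanism, but the observable is the allele pair. The
  generator still plants its inversion with inverted-repeat flanks as a
  stem-loop mimic.

A column with fewer than two observed states (e.g. one base plus `N`s) is
invariant. Pairwise differences use SNP sites only, counting sites where
both members of a pair are observed and differ; with missing data the
triangle inequality can fail, and the count is bounded by the pair's
complete-case sites — both properties are asserted in the tests.

## Coding effects

Effect annotation assembles the codon across exon boundaries in
transcription order, reverse-complements for minus-strand features,
honours the codon phase, and translates with the bacterial/plastid
genetic code (table 11, via `Biostrings::getGeneticCode("11")`; it
differs from the standard code only in start-codon treatment, which does
not affect substitution calls beyond position 1). An allele creating a
premature stop is reported as `alt_aa == "*"`, not an error; an
incomplete terminal codon is an error naming the feature. Pseudogenes are
never translated.

Amino-acid property classes use a five-class scheme: basic `R K H`,
acid/amide `D E N Q`, hydrophilic `S T A P G`, hydrophobic
`V I L M F W Y`, special `C`. This is the unique total mapping family
consistent with the eight published chloroplast substitution rows this
package reproduces (R and K basic; Q acid/amide; S, A, P hydrophilic;
V, I, L hydrophobic; C its own class — the source table's "Cytosine"
entry for the R→C row is read as the residue cysteine); remaining
residues follow standard groupings. Note that placing S and A together as
"hydrophilic" disagrees with Kyte–Doolittle hydropathy — we follow the
published scheme, not a hydropathy scale, and the scheme is an ordinary
named vector that callers can replace.

## Mitochondrial robustness and anti-paralogy filtering

Sites scored from short contigs carry missing data and paralogy risk. The
robustness rule keeps a site iff

- observed in ≥ 6 individuals **and** the second variant occurs ≥ 3
  times (partial-coverage rule), **or**
- observed in *all* individuals **and** the second variant occurs ≥ 2
  times (full-coverage rule).

"Unambiguously represented" is interpreted as a non-missing, non-ambiguous
base call; individuals, not contigs, are counted. At multi-allelic sites
the second-most-frequent allele is tested and further alleles are
ignored. The rule is monotone (adding a minor-allele observation never
rejects a kept site) and order-invariant — both are tested properties.

A locus is flagged as paralog-contaminated when any single individual
contributes two or more aligned contig copies disagreeing at ≥ 1 site
(strictest reading, configurable): a haploid organelle cannot carry two
alleles, so within-individual disagreement indicates co-aligned paralogs,
which would inflate diversity downstream. Flagged loci are dropped before
the robustness filter.

## Diagnostic markers and amplicon windows

A site is group-diagnostic when every *observed* member of group A shares
one base, every observed member of group B shares a different base, and
each group is observed at least `min_obs_per_group` times (default 2 — a
1-observation default would promote singletons to "diagnostic"; the
bundled published matrix still reaches ≥ 2 observations per group at its
sparsest column). The outgroup row never enters the partition test; its
allele is recorded to polarise variants. Because missing entries are
ignored, calls on sparse matrices are *putatively* diagnostic — the same
caveat the source data carries.

Amplicon evaluation searches for the shortest window of length ≥
`min_len` (default 60) containing the site whose two terminal
`flank_len`-column stretches (default 20) are invariant across all
samples and gap-free; windows longer than `max_len` (default 150) are
rejected. The 60–150 nt range is the practical envelope for degraded
sedimentary ancient DNA that still permits melt-curve screening; 20 nt is
a typical primer footprint. Among equal-length windows the most
site-centred placement wins, ties going left — an arbitrary but
deterministic choice.

## Statistical parsimony networks

Individuals with identical complete-case SNP profiles collapse into
haplotypes (mirroring the use of fully observed sites only; with partial
profiles, identity is undefined, so the function refuses missing data).
The probability of parsimony for `j` mutational steps over `m` sites is
computed as the exact probability that `j` mutations placed independently
and uniformly over `m` sites all strike distinct sites:

$$P(j, m) = \prod_{i=0}^{j-1}\left(1 - \frac{i}{m}\right),$$

i.e. the probability that the observed differences involve no
superimposed (multiple-hit) changes. This is the package's own estimator
of the classic statistical-parsimony connection criterion; it assumes a
uniform mutation rate across sites and neglects back-mutation along the
path (which would make haplotypes look *closer*, so the limit errs
conservative). It is cross-checked in the tests against an independent
Monte Carlo placement simulation. The connection limit at confidence `c`
(default 0.95) is the largest `j` with `P(j, m) ≥ c`; it is
non-decreasing in `m`, non-increasing in `c`, and collapses to 1 as
`c → 1`. `m` is the alignment length of the underlying molecule, not the
SNP count — consistent with the method's definition — and is exposed as a
parameter since published analyses do not always state which was used.

Network construction iterates the candidate distance `d = 1..limit`: each
observed haplotype pair at profile distance `d` not yet connected by a
path of ≤ `d` edges is joined by a path of `d` unit-mutation edges with
`d − 1` inferred intermediates; an intermediate profile matching an
existing node (observed or inferred) reuses that node, and this reuse is
what creates loops (alternative genealogical pathways). Pairs beyond the
limit stay in separate components. Two tie-breaks make the output
deterministic: pairs at equal distance are processed in lexicographic
haplotype-id order, and intermediate profiles mutate the differing sites
in ascending site order. The reference implementation's internal order is
unspecified, so exact topology equality with published figures is not a
testable property — structural invariants are (unit-step edges,
multiplicity conservation, inferred nodes on shortest paths, determinism),
and the construction is verified against an independent brute-force
implementation on all test fixtures of ≤ 6 haplotypes over ≤ 10 sites.

## The synthetic study and what it does (not) show

`simulate_alignment_set` emulates the study conditions end to end: 19
individuals in three regions (12/4/3), a 20 kb toy circular genome with
annotated genes (one multi-exon, one reverse-strand, plus tRNA, rRNA and
pseudogene features), 84 planted SNPs with a 44% transition share of
which 8 are group-diagnostic with wide conserved flanks, 5 InDels (one an
insertion absent from the reference), 17 homopolymer-length differences
and one 3-nt stem-loop inversion (`AGA`↔`TCT`) with inverted-repeat
flanks. Reference GC content defaults to 38.74%; coding regions are
drawn codon-uniform, so realised GC runs slightly higher. About 32% of
SNPs (27 of 84) are placed in coding sequence, mirroring the observed
coding fraction. Carrier counts favour singletons (70%), echoing the
observed predominance of unique variants. Events are mutually disjoint,
kept ≥ 50 nt from the alignment ends, and spaced so that adjacent
substitution columns cannot masquerade as inversions; infeasible
configurations fail before generation. Same seed, same bytes: generation
is integer/character-based with R's RNG, so outputs are reproducible
across platforms.

`simulate_mito_matrix` produces the mitochondrial-style counterpart: 60
sites across 10 loci, 8 diagnostic sites that always retain ≥ 2
observations per group under masking, exactly 16 fully observed
(complete-case) sites when missingness is on, per-cell missingness 0.2,
and 2 paralog-contaminated loci in which one individual carries two
contig copies differing at 3 sites.

Passing tests on these simulations demonstrate correctness of the
*bookkeeping* — event partitioning, classification, coordinate and codon
arithmetic, filter logic, network construction — under a known truth.
They do not demonstrate robustness to what real data adds: alignment
errors around repeats, coverage-correlated missingness, recurrent
mutation, or genealogical structure among carriers (planted carrier sets
are independent across sites, which is why simulated networks contain
many more inferred intermediates than tree-like real data).

## Problem sizes and numerical choices

The test suite runs the full 19 × 20 kb configuration across 100 seeds
for exact parameter recovery, a 19 × 120 kb / 2000-SNP configuration for
the transition-share check (within three binomial standard errors of
0.44), 200 random matrices against the exhaustive diagnostic oracle, and
brute-force network comparisons on ≤ 6-haplotype fixtures — sizes chosen
to exercise every code path at desk scale while keeping a full run in the
low minutes. Determinism everywhere rests on explicit tie-breaks rather
than hash or pointer order: lexicographic minor alleles, ascending-site
intermediate generation, lexicographic pair processing, and stable site
and sample ordering in all tables.

## Limitations

- Alignment columns are linear; origin-spanning events are not modelled.
- `N` is the only ambiguity state; partial IUPAC information is discarded.
- The parsimony probability ignores rate heterogeneity across sites and
  back-mutation; the connection limit is therefore approximate, as any
  single-number criterion is.
- Median-joining and minimum-spanning network variants, primer
  thermodynamics, and annotation discovery are out of scope.
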