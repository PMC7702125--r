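---
title: "Methods: desk-scale genome-evolution scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale genome-evolution scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoscan)
```

`evoscan` implements the analyses that turn a finished plant genome assembly
into evolutionary statements: when the genome last duplicated, when its LTR
retrotransposons burst, where its centromeres sit, which gene families
expanded in tandem, and which candidate genes respond across developmental
stages. This vignette is the package's own account of those methods — the
models, their assumptions, the tunable parameters, and the choices made where
the methods literature leaves the design open.

## 4DTv and whole-genome duplication dating

A fourfold-degenerate (4D) site is a codon third position at which all four
nucleotides encode the same amino acid. Eight two-base codon prefixes define
such families in the standard code (`GC`, `CG`, `GG`, `CT`, `CC`, `TC`,
`AC`, `GT`). Because every change at a 4D site is synonymous, divergence
there is approximately neutral, and because transversions (purine ↔
pyrimidine) accumulate more slowly than transitions, the *transversion*
fraction at 4D sites — 4DTv — remains informative deeper into the past than
overall synonymous distance.

For a codon-aligned paralog pair, a third-position column is counted iff
both codons are gap-free and unambiguous, agree at positions 1–2, and share
a fourfold prefix. This is the strict reading: a codon fourfold-degenerate
in only one of the two sequences is excluded, since its third position is
not guaranteed synonymous in both. Raw 4DTv is transversions per 4D site.

The raw fraction saturates: under any stationary model the expected
transversion fraction tends to $2\pi_R\pi_Y$ (purine frequency times
pyrimidine frequency, times two). We correct with the transversion-distance
component common to the HKY85/TN93 family,

$$\hat d_{tv} = -2\pi_R\pi_Y \log\!\left(1 - \frac{Q}{2\pi_R\pi_Y}\right),$$

which estimates the expected number of transversions per site and reduces to
$-\tfrac12\log(1-2Q)$ at equal base frequencies. Base frequencies are pooled
over both sequences at the 4D sites of the pair. Pairs whose raw fraction
reaches the $2\pi_R\pi_Y$ boundary are flagged saturated and excluded from
the corrected distribution (they remain usable for raw-value histograms).
The HKY-family choice matters only through $\pi_R\pi_Y$: any model in that
family with the same stationary frequencies yields the same transversion
distance, which is why no transition/transversion ratio needs to be
estimated.

Parameters:

- `min_4d_sites` (default 10): pairs with fewer 4D sites give fractions too
  granular to bin meaningfully; excluded pairs are counted, not silently
  dropped.
- `bin_width` (default 0.02 on a [0, 2] scale): the distribution peak is the
  midpoint of the modal bin, leftmost on ties (ties are flagged). A modal
  bin is a deliberately simple peak estimator; with per-pair standard errors
  around 0.08 at distances near 0.5, the modal bin is reproducible only to
  about one bin, and the package's own calibration tests assert exactly
  that one-bin resolution rather than pretending to more.
- Input pairs must arrive aligned in codon frame. The package does not build
  codon alignments: paralog pairs from synteny pipelines come aligned, and
  silently aligning them here would hide a consequential modelling step.

## LTR insertion-age dating

At insertion the two long terminal repeats of a retrotransposon are
identical; each subsequently accumulates substitutions independently. With
inter-LTR divergence $K$ (substitutions/site) and a substitution rate $r$
(substitutions/site/year), the insertion age is $T = K/(2r)$ — the factor 2
because both LTRs drift.

The observed mismatch fraction $p$ is computed over comparable columns only:
columns with a gap or ambiguity character in either sequence are excluded
from numerator and denominator, since indel placement is an alignment
artefact rather than substitution evidence. $K$ is the Jukes–Cantor
correction $-\tfrac34\log(1-\tfrac43 p)$, undefined (saturated) at
$p \ge 0.75$; saturated elements are excluded from dating and counted.
Jukes–Cantor is the conventional choice for LTR dating — inter-LTR
divergence is small (a few percent for elements younger than ~5 Mya), where
all reversible models agree to first order.

Parameters: `rate` defaults to $1.3\times10^{-8}$ substitutions/site/year,
the general plant nuclear rate; ages are reported in Mya and binned at 0.25
Mya by default for burst histograms. Unaligned pairs can be aligned with a
global affine-gap aligner (match 1, mismatch −1, open 2, extend 0.5, via
`Biostrings::pairwiseAlignment`); the aligner is pluggable in the sense that
callers may supply pre-aligned pairs from any tool.

## Centromeric satellite detection

Plant centromeres are dominated by a high-copy tandem repeat with a monomer
typically 150–180 bp. The scan has four stages:

1. **Cluster** Tandem Repeats Finder monomers. Monomer phase is arbitrary
   and strand is meaningless for a tandem array, so identity between two
   monomers is the best local alignment of one monomer — and of its reverse
   complement — against the other monomer doubled (doubling contains every
   rotation), divided by the shorter monomer length. Single-linkage greedy
   clustering joins monomers at ≥ 0.80 identity; records are canonically
   sorted first so clustering is independent of input order. Periods are
   restricted to 50–500 bp, the band containing typical centromeric
   satellites.
2. **Base repeat**: the cluster covering the most genomic bases; ties break
   to the longer representative monomer. The representative is the member
   with the highest copy number.
3. **Map** the representative across both strands of the genome. The
   internal scanner finds full-length copies within a mismatch budget of
   $(1-\text{min\_identity}) \times$ monomer length; because it reports only
   full-length matches, a separate coverage threshold (default 0.90 of the
   monomer) becomes active when externally produced tabular hits (e.g.
   BLASTN, where an E-value/overlap filter is natural) are supplied instead.
4. **Call** per-chromosome centromeres: satellite bp summed in non-overlapping
   300-kb windows; the maximal window is merged with flanking windows holding
   at least half its density; a chromosome whose best window carries less
   than `min_fraction` (default 0.05) satellite sequence is reported
   `no_call` — real assemblies have chromosomes with no discernible
   satellite peak, and an honest scanner must be able to say so. The 0.05
   floor is this package's operationalisation of "has a narrow peak"; it is
   exposed as a parameter because no standard definition exists.

GC content is reported for the representative monomer alone, matching how
satellite monomers are described in assembly reports.

## Gene-family screening and tandem arrays

Candidate family members must satisfy, in one homology hit: E-value ≤ 1e-5,
alignment identity ≥ 50%, and alignment coverage ≥ 50% of the query — all
inclusive bounds — and must carry the query's Pfam domains. "Carries the
query's domains" is interpreted as superset (extra domains do not
disqualify); an exact-equality mode exists for stricter screens. LEA
subfamily classification maps seven diagnostic Pfam domains (PF03760 → LEA1,
PF03168 → LEA2, PF03242 → LEA3, PF02987 → LEA4, PF00477 → LEA5, PF00257 →
dehydrin, PF04927 → SMP) with a *strict* E < 0.01 threshold. The asymmetry —
inclusive ≤ for the homology filter, strict < for the domain screen — is
preserved deliberately because that is how the two filters are conventionally
stated.

Tandem arrays: within a chromosome, family members sorted by start chain
when consecutive members are ≤ 100 kb apart (start-to-start) and separated
by ≤ 5 non-member genes; maximal chains of ≥ 2 are arrays, reported with
their genomic span. There is no universal operational definition of "tandem
array"; these defaults reproduce the canonical example of ten 3-ketoacyl-CoA
synthase (KCS) genes clustered in 0.27 Mb while rejecting members megabases
apart, and both knobs are exposed.

## Expression summaries

RPKM is `counts × 10⁹ / (library_size × gene_length)`. The heat-map
transform is `log10(RPKM + 1)` with values at RPKM ≤ 1 floored to exactly 0
— a display rule, not a continuous function, and the package deliberately
reproduces the discontinuity (the value at RPKM = 1 is 0, not log10(2)).
Stage fold changes average replicates on the RPKM scale within stage and add
a pseudocount (default 1 RPKM) to both means; genes are ranked by descending
fold. Significance testing is out of scope: fold-plus-rank is the nomination
rule, with testing left to dedicated count-model packages. Row z-scores
standardise each gene across samples, with zero-variance rows set to zero
and flagged. qPCR relative expression is $2^{-\Delta\Delta C_t}$ with
replicate $C_t$ values averaged per sample, the target gene normalised to a
reference gene, and a calibrator sample defining the unit.

## The synthetic-data module

Every generator is a pure function of its parameters and a seed, restores
the global random stream, and emits files that parse through the package's
own readers. What each emulates, and what it does not:

- **Codon pairs** descend from an ancestor whose codons are drawn from
  fourfold families (with a 0.2 decoy fraction of non-fourfold codons to
  exercise site classification); positions 1–2 are copied, third positions
  evolve down two branches under the exact HKY85 transition matrix
  (spectral form), so the expected transversion fraction is computable in
  closed form and oracle-testable. `distance_scale = "transversion"` lets a
  caller plant a target transversion distance directly. Not emulated:
  selection on codon usage, dN/dS, alignment error.
- **LTR cohorts** evolve two copies of a random ancestral LTR under exact
  Jukes–Cantor site dynamics for a given age and rate. Not emulated:
  nesting, truncation, gene conversion between LTRs (which in real data
  biases ages young).
- **Satellite chromosomes** plant a tandem array of independently mutated
  monomer copies (default monomer length 161 bp, the typical maple-like
  satellite period; content random per seed) in a uniform-random background,
  plus low-copy decoy repeats, and emit the matching TRF table. Not
  emulated: higher-order repeat structure, satellite islands outside the
  centromere.
- **Family fixtures** give every true member a hit passing all thresholds
  plus the query domain, and give each decoy a violation of exactly one
  criterion — so the screen's output must equal the truth set exactly, and
  any single-threshold regression flips a labelled decoy.
- **Expression fixtures** draw negative-binomial counts (size 100, i.e. a
  10% biological CV, typical of well-controlled replicated RNA-seq) with
  lognormal gene means, three replicates per stage, and explicit library
  sizes of 10⁶ reads per sample (the fixture is the counted subset of a
  full transcriptome, so column sums would understate sequencing depth).
  Planted up-regulated genes sit at high baseline expression, like the
  seed-development marker genes whose fold changes the fixture emulates;
  fold recovery to within 20% is only well-posed away from the
  counting-noise floor, and the generator encodes that condition rather
  than asserting it of genes where it cannot hold.

Because the generators use idealised substitution processes and uniform
backgrounds, passing recovery tests demonstrates correctness of the
estimators under their own model assumptions — not robustness to alignment
error, compositional heterogeneity, or repeat nesting in real genomes.

## Numerical and design choices

- Coordinates are 1-based inclusive throughout, the convention of GFF3, TRF
  and the R/Bioconductor ecosystem; readers and writers therefore perform no
  coordinate arithmetic at the boundary.
- Rate matrices are exponentiated by spectral decomposition of the
  reversibly symmetrised matrix — exact, stable, and independently checked
  in the tests against a dense matrix exponential.
- Multiple HSPs per query–subject pair collapse to the lowest E-value, ties
  to the highest bit-score.
- Percentages that mirror printed tables round half-up (printed-table
  convention), not to even (R's default).
- Histogram peaks are modal bins, leftmost on ties, with ties flagged;
  no kernel smoothing, so the resolution is explicit (one bin) rather than
  bandwidth-dependent.
- Problem sizes in the test-suite simulations (500 × 300-codon pairs, 200
  1-kb LTRs, 1.5-Mb satellite chromosomes with 300 monomer copies, 50-gene
  family fixtures, 200-gene expression fixtures over 20 seeds) were chosen
  as the smallest cohorts at which the stated statistical tolerances (3
  standard errors; one histogram bin; exact set recovery; ≥ 95% top-k rate)
  are comfortably met by the estimators' sampling theory.

## Known limitations

- The 4DTv correction assumes stationarity and shared base composition
  between paralogs; strongly GC-shifted duplicates would need a
  nonstationary model outside this package's scope.
- The modal-bin peak does not decompose overlapping WGD peaks; mixture
  modelling of the corrected distribution is deliberately out of scope.
- The satellite mapper's internal scanner matches full-length monomers with
  substitutions only; arrays diverged by large indels or higher-order
  structure should be mapped with an external aligner and supplied as a hit
  table.
- The screen is query-agnostic: it evaluates evidence tables, and the
  biological adequacy of the query set is the caller's responsibility.
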