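# evoscan

Desk-scale genome-evolution analyses for newly assembled plant genomes,
implemented as a tidyverse-native R package. `evoscan` covers the light-weight
computations that accompany a chromosome-scale assembly project once the heavy
lifting (assembly, gene prediction, repeat discovery) is done:

- **Whole-genome duplication dating by 4DTv.** For codon-aligned paralog
  pairs, the fraction of fourfold-degenerate third-codon sites that differ by
  a transversion, `4DTv = 4DT / 4D`, corrected for multiple hits with the
  transversion-distance component of the HKY/TN93 model family,
  `-2 π_R π_Y log(1 - Q / (2 π_R π_Y))`. Peaks of the paranome distribution
  mark WGD events (the γ hexaploidy of core eudicots sits near 0.5).
- **LTR retrotransposon insertion ages.** The two LTRs of an element are
  identical at insertion; from their divergence `p`, the Jukes–Cantor distance
  `K = -3/4 · log(1 - 4p/3)` and the insertion age `T = K / (2r)` with
  `r = 1.3 × 10⁻⁸` substitutions/site/year give burst histograms.
- **Centromeric satellite detection.** Tandem Repeats Finder monomers are
  clustered with rotation- and strand-invariant identity; the dominant
  ("base") repeat is mapped genome-wide and per-chromosome density peaks in
  300-kb windows localise putative centromeres.
- **Rule-based gene-family screening.** The two-criterion homology filter
  (E ≤ 1e-5, identity ≥ 50%, query coverage ≥ 50%) plus shared-Pfam-domain
  requirement; LEA subfamily classification by diagnostic domains (PF03760 =
  LEA1 … PF04927 = SMP, E < 0.01); tandem gene-array detection on gene
  coordinates.
- **Expression summaries.** RPKM, the `log10(RPKM + 1)` transform with
  RPKM ≤ 1 floored to 0, stage fold changes, per-gene z-scores, and qPCR
  `2^-ΔΔCt`.
- **Assembly statistics.** Nxx, completeness percentages (half-up rounding,
  as printed in assembly tables), GC content.

Every input the pipeline consumes (FASTA, GFF3, BLAST outfmt-6, TRF `.dat`,
HMMER domtblout, count matrices) can be generated by the built-in
synthetic-data module with recorded ground truth, so the whole pipeline is
testable without downloading any deposited data.

## Worked example

```r
library(evoscan)

# simulate 500 paralog pairs at a true transversion distance of 0.5
sim  <- simulate_codon_pair_set(n_pairs = 500, n_codons = 300, distance = 0.5,
                                distance_scale = "transversion", seed = 7)
scan <- paranome_4dtv(sim$pairs)
scan
#> Paranome 4DTv distribution (corrected values)
#>   pairs used: 500  excluded: 0
#>   peak: 0.49 (bin width 0.02 )
```

The modal bin midpoint 0.49 sits within one 0.02-wide bin of the simulated
transversion distance 0.5 — the statistical resolution of a modal-bin peak at
this cohort size. `tidy(scan)` returns the per-pair table (4D site counts,
transversions, raw and corrected 4DTv), `autoplot(scan)` the histogram.

```r
ltr  <- simulate_ltr_cohort(n = 200, ages_mya = 1.5, ltr_length = 1000, seed = 7)
prof <- age_profile(ltr_ages(ltr$pairs))
glance(prof)
#> # A tibble: 1 × 7
#>   n_elements n_dated n_saturated mean_age_mya burst_peak_mya peak_tied bin_mya
#>        <int>   <int>       <int>        <dbl>          <dbl> <lgl>       <dbl>
#> 1        200     200           0         1.49           1.38 FALSE        0.25

insertion_time(K = 0.026) / 1e6   # years -> Mya at the default rate
#> [1] 1

completeness_percent(239, 248, 2) # CEGMA-style completeness
#> [1] 96.37
```

The cohort mean recovers the planted 1.5-Mya insertion age to within its
standard error; a divergence of `K = 0.026` dates an element at exactly
1.0 Mya under the default substitution rate.

An end-to-end demonstration over every stage, with a machine-readable
truth-vs-estimate report, is one call:

```r
report <- run_demo(seed = 42, outdir = "demo_out")
report$all_pass
#> [1] TRUE
```

A thin command-line front end with subcommands (`simulate`, `4dtv`,
`ltr-age`, `censcan`, `famscreen`, `expr`, `stats`, `run-demo`) is installed
at `inst/cli/evoscan.R`.

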