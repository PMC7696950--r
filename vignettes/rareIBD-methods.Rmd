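---
title: "Detecting shared IBD segments from very rare alleles: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shared IBD segments from very rare alleles: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareIBD)
```

## The model

Two individuals who inherited a chromosomal fragment from a common ancestor
carry identical sequence over that span — an identical-by-descent (IBD)
segment. Within such a span, any very rare SNP allele carried by one is
carried by the other, so a *cluster of neighbouring shared very rare
alleles* marks an IBD segment without any phasing or haplotype modelling.
`rareIBD` operationalizes this idea:

1. **Very-rare-allele database.** From a primary cohort, every alternate
   allele with frequency at or below a threshold (0.3% by default; allele
   copies over called allele copies) enters the database with its carrier
   list; all other observed alternates form the complementary non-rare
   database. Small secondary cohorts cannot estimate frequency reliably, so
   their alleles are first rejected against the non-rare database (a batch-
   effect guard between sequencing projects) and then accepted only below
   an absolute minor-allele copy cap (4 for an SGDP/EGDP-sized project, 2
   for a still smaller one). Ancient genomes contribute only alleles
   matching the finalized modern database; they never influence frequency.

2. **Detection.** Each individual's database entries form a sorted marker
   track. For a pair, a shared IBD segment is a maximal run of at least
   `min_markers = 5` markers present in both tracks. Five markers keep the
   identical-by-state noise floor negligible, at the price of missing
   segments shorter than roughly 20 kb (marker density in real data is
   about one per 10 kb).

3. **Population statistics.** Segment counts are averaged per individual
   pair between (and within) populations; counts are freed from
   cohort-to-cohort differences in detected marker abundance by
   `J_AB = I_AB / sqrt(N_A N_B)`, where `N` is each population's mean
   per-individual marker count relative to the across-population average.
   Mean segment lengths are always reported; medians only from five pooled
   segments upward.

4. **Apportionment.** Each population's normalized sharing with three
   reference populations per world region is summed — per-pair values
   capped at 100 to damp founder-effect inflation in small inbred
   populations — and rescaled to percentages totalling 100.

5. **Dating.** The recombination clock `L = C/(2 g r)` links the median
   shared-segment length `L` (Mb) of a modern pair to the generations `g`
   since the last common ancestor, with `r` the genome-average
   recombination rate per Mb and `C ≈ 2` an empirical constant absorbing
   recombination-hotspot reuse, calibrated on dated ~8000-year-old European
   genomes (`C = 320 × 0.0118 × 0.585 ≈ 2.209`). Ancient-vs-modern
   comparisons drop the factor 2: between two moderns only the intersection
   of two independently transmitted segments is observable, which on
   average halves the length.

## Interruption policy

The sources describing the five-marker rule do not state what happens when
a rare allele carried by exactly *one* of the two individuals falls inside
a candidate run. The package's default (`"strict"`) breaks the run there: a
non-shared very rare allele inside a truly identical span is unexpected, so
tolerating it would chain independent segments together. A `"lenient"`
mode that ignores private markers is provided for sensitivity analysis.
Similarly, no maximum gap between neighbouring shared markers is enforced
by default (`max_gap = Inf`), with a configurable limit exposed. Both
policies are implemented twice — the production scanner and an exhaustive
window enumerator — and the test suite holds them equal on thousands of
randomized pairs.

## Coordinates, units, rounding

Segment coordinates are 1-based inclusive; `length_bp = end − start + 1`,
with `start`/`end` the first and last shared markers. Lengths are stored in
bp, region medians printed in kb, dating in thousands of years at one
decimal. Published dating tables print some large cells as integers, which
can differ from the 1-decimal formula output by up to ~0.7 ky (consistent
with unrounded upstream medians); the package keeps one decimal everywhere
and documents the divergence rather than reproducing it. Undefined cells
(singleton-population diagonals, medians under five segments,
ancient–ancient datings) are `NA` in memory and the literal `N/A` in
emitted tables.

## The synthetic generator and what it does (not) emulate

`synthetic_config()` describes desk-scale cohorts: 2 chromosomes × 50 Mb,
six populations of ten individuals, and individual-private markers placed
as a Poisson process at `1e-4` per bp (one per 10 kb, the empirical density
of very rare alleles). Planted segments receive shared markers at the same
density across their span, assigned to both pair members; a 100 kb planted
segment therefore carries Poisson(10) markers and is recovered by the
five-marker rule in ≈97% of draws, which the acceptance suite verifies over
100 seeds. Two deliberate design choices:

* **Frequency threshold scales with cohort size.** Sixty diploids cannot
  host a 0.3%-frequency allele — even a singleton sits at 0.83%. The
  generator therefore carries its own `rare_threshold` (default 5%, under
  which a pair-shared planted allele at 2/120 ≈ 1.7% passes), and it
  *errors*, reporting the minimum cohort size, whenever a generated allele
  would break the configured guarantee. The production default of 0.3%
  remains on `build_core_rare_db()`.
* **No private markers inside planted spans.** A truly IBD span contains no
  non-shared very rare alleles, so the generator suppresses the two
  members' private draws inside each planted span; otherwise the strict
  policy would fragment every planted segment (~10 expected interruptions
  per 100 kb) and planted-truth recovery would be meaningless.

The generator emulates population-private rare variation, planted sharing
of known span and depth, ancient samples whose usable alleles are a subset
of the modern pool (`plant_ancient()`, which copies runs of consecutive
donor markers), and chance identical-by-state collisions. It does **not**
model drift, mutation-rate variation, linkage disequilibrium, recombination
hotspots, or realistic site-frequency spectra — passing tests demonstrate
the pipeline's correctness on its own assumptions, not calibration against
real cohorts. `sample_ibd_lengths()` draws segment lengths from an
exponential whose median equals the calibrated clock's `C/(2 g r)` — chosen
over the textbook `ln 2/(2 g r)` mean-parameterization so that dating
validation is self-consistent with the calibrated constant.

## Numerical and degenerate-input choices

* The very-rare boundary is inclusive (`frequency ≤ threshold` is rare).
* Allele identity for matching is `(chrom, pos, alt)`; `ref` is validated
  at ingestion but not part of the key, as cohorts share a reference build.
* Secondary-cohort acceptance counts minor-allele *copies* (not carrier
  individuals); the cap is configurable. When two secondary cohorts accept
  the same key, carriers are unioned and the first provenance kept, making
  the database independent of processing order.
* A homozygous carrier is one carrier contributing two allele copies.
* Normalization uses the unweighted mean over populations as the grand
  average; coefficients then average to exactly 1.
* Apportionment errors on an all-zero row rather than emitting undefined
  percentages; a population serving as its own region's reference includes
  its intra-population cell (configurable via `include_self`).
* In the MDS transform `d = (1 − s)/s`, zero similarities (which would be
  infinitely distant) are replaced by half the smallest positive
  similarity; the diagonal is 0 by definition. Ranking ties break
  lexicographically by population identifier.

## Problem sizes

The test and acceptance suites run the generator at the default
2 × 50 Mb / 60-individual scale for the 100-seed recovery and null-model
checks (~600,000 markers per cohort), and at reduced scales (2 × 5–10 Mb,
12–54 individuals) where only structural laws are exercised. These sizes
were chosen so a full validation pass completes in minutes on one core
while keeping every statistical check at the power the claims require.

## Known limitations

* The scanner is exact but quadratic in the number of profiles; the
  4.9-million-pairing scale of consortium data is reachable but slow in
  pure R — the per-pair detector is the natural unit for parallelization.
* Chance-level sharing is quantified empirically via the random-genome
  null; the package does not re-derive the analytic false-positive bound
  for the five-marker rule.
* Region reference maps (the nine-region configuration and its three
  reference populations each) are inputs, not discovered structure.
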