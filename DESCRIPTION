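Package: rareIBD
Title: Shared Identity-by-Descent Segments from Clusters of Very Rare SNP Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects identical-by-descent (IBD) chromosomal segments shared
    between pairs of unphased genomes as clusters of at least five neighbouring
    very rare SNP alleles, and aggregates them into population-level
    relatedness statistics. Builds a very-rare-allele database from a primary
    genotype cohort (frequency at or below 0.3% by default), extends it with
    count-filtered alleles from secondary cohorts and matched alleles from
    ancient genomes, scans all individual pairings for shared-allele clusters,
    and derives population-by-population matrices of IBD counts and lengths
    with cross-cohort normalization. Downstream tools apportion each
    population's relatedness over nine reference world regions, rank sharing
    partners, date last common ancestors from median segment lengths with a
    calibrated recombination-clock formula, quantify chance-level sharing with
    a random-genome null model, and project individual relatedness to two
    dimensions by classical multidimensional scaling. A seeded synthetic-data
    generator produces desk-scale cohorts with population-private rare alleles
    and planted IBD segments of known age for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
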