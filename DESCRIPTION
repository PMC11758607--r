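Package: poptrace
Title: Population-Diagnostic SNP Marker Discovery and Wildlife Sample Traceability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for genome-based geographic traceability of wildlife
    samples. Screens multi-sample VCFs for population-diagnostic SNPs
    (loci fixed for a private allele), after flagging duplicate and
    first-degree relatives with a KING-robust kinship estimator and
    screening gene flow with Patterson's D (ABBA-BABA) and a block
    jackknife. Ranks marker-bearing genes by Robinson-Foulds concordance
    of gene trees with a species tree, extracts flanking sequence around
    diagnostic loci, designs PCR primer pairs under Primer3-style
    constraints with nearest-neighbor melting temperatures, validates
    them by in-silico PCR, and assigns unknown samples to a population
    from their diagnostic alleles. Includes a Balding-Nichols cohort
    simulator and a mitochondrial haplotype network builder
    (minimum-spanning), so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vcfR,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph
Config/testthat/edition: 3
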