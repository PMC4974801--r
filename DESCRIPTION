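Package: rhizopop
Title: Population Genomics of a Localized Clonal Rhizobial Population
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diversity and demographic analysis of closely related haploid
    bacterial genomes, built around a localized clonal Sinorhizobium
    meliloti population. Classifies single-nucleotide polymorphisms into
    synonymous, non-synonymous and intergenic classes with a codon
    degeneracy based null expectation; computes Watterson's theta,
    nucleotide diversity, Tajima's D (also per synonymous and
    non-synonymous site class), Fu and Li's D* and F*, Fu's Fs and the
    Ramos-Onsins and Rozas R2 statistic with coalescent-simulation
    significance; fits the sudden-expansion mismatch-distribution model
    (theta0, theta1, tau) with Harpending's raggedness index and converts
    mutational time tau to calendar years under a strict molecular clock.
    Includes an infinite-sites coalescent simulator with constant-size,
    sudden-expansion and exponential-growth demographies, and a generator
    of codon-structured toy genomes with planted variants of known class.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
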