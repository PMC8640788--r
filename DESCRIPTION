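Package: fragilescan
Title: Non-B DNA Motifs, Hairpin Thermodynamics, and SNP Spectra at
    Replication Pause Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for characterising replication pause sites at common
    fragile sites from sequence alone: detection of the five classical non-B
    DNA motif classes (inverted repeats/cruciforms, mirror-symmetric
    homopurine-homopyrimidine triplex motifs, direct and tandem repeats,
    Z-DNA-favouring alternating purine-pyrimidine tracts, and G-quadruplex
    motifs), per-interval motif censuses with mean + k*SD enrichment flags,
    windowed minimum-free-energy hairpin folding under a documented
    nearest-neighbour DNA model, window composition (%C+G, TT dinucleotides),
    SNP densities and strand-collapsed six-class mutational spectra with
    T>(C+G) and C>(A+T) aggregates, quantile binning of variant density
    against folding energy, Mann-Whitney group comparisons, and randomised
    10-kb window nulls. Includes a seeded synthetic-study generator that
    emulates a multi-segment fragile-site locus with planted motifs, pause
    annotations, and simulated SNPs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
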