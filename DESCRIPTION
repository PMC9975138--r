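Package: introPaint
Title: Chromosome Painting, ABBA-BABA Tests and Haplotype-Based Selection
    Scans for Introgression Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises introgression between diverged gene
    pools from phased biallelic SNP data. Implements supervised chromosome
    painting by per-window principal component analysis with kernel density
    classification against reference panels, frequency-based ABBA-BABA tests
    (Patterson's D with block-jackknife standard errors, admixture fraction
    f, and windowed fd/fdM), sliding-window diversity statistics (nucleotide
    diversity, Dxy, Hudson and Weir-type Fst, Tajima's D), and an iHS scan
    based on extended haplotype homozygosity with candidate-gene mapping.
    Includes a seeded synthetic-data generator that emulates strongly
    diverged gene pools with planted introgression tracts and partial
    selective sweeps, with machine-readable truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
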