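Package: haplodesign
Title: Validation of Polyploid Genome Design Crosses from Haplotype-Specific Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate polyploid genome design in crops that propagate
    clonal (unreduced, nonrecombined) gametes through a mitosis-instead-of-meiosis
    system. Derives haplotype-unique SNP markers for two- and four-haplotype
    crossing designs by set algebra over variant call sets, computes sliding-window
    B-allele-frequency, coverage and SNP-density profiles, classifies offspring as
    clonal or recombinant with crossover breakpoint calls, detects aneuploidy and
    chromosome truncation from joint allele-frequency and coverage deviation,
    validates haplotype presence by marker recovery, and genotypes gene dosage in
    tetraploids. A forward simulator of the full crossing scheme (inbred founders,
    F1 hybrids, clonal or meiotic gametes, tetraploid double-cross offspring,
    binomial read sampling) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
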