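Package: founderhap
Title: Founder-Haplotype Detection, Recombination-Clock Dating and
    Autozygosity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing founder mutations from multi-sample
    genotype data: detection of the ancestral haplotype shared by
    unrelated homozygous carriers of a focal variant, dating of the
    founder event from the exponential decay of one-sided haplotype
    genetic lengths, Hardy-Weinberg homozygote-excess testing, cohort
    allele-frequency and incidence arithmetic, and a shared
    runs-of-homozygosity scan for autozygosity mapping in consanguineous
    pedigrees.  Includes a founder-cohort simulator with a recorded truth
    log so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
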