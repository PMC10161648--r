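Package: markergt
Title: Pangenome Genotyping with a Suffix-Rank-Ordered Marker Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Indexes a panel of phased haplotypes with a Burrows-Wheeler
    transform and FM-index augmented by a "smeared" marker array that stores,
    in suffix-rank order, the polymorphic sites overlapped by each text
    position and a short window to its right. Short sequencing reads are
    scanned right-to-left with a heuristic backward-search algorithm that
    consults the marker array at regular intervals to collect allele evidence
    at known polymorphic sites, from which haploid majority-vote and diploid
    likelihood-based genotypes are called. Includes a reproducible simulator
    for haplotype panels, diploid donors and error-bearing short reads with
    complete truth, plus precision/recall evaluation of the resulting calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
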