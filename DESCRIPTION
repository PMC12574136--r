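Package: fragmeth
Title: CpG-Island Methylation Status from WGS Fragmentation Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the methylation status of CpG islands from ordinary
    whole-genome sequencing alignments, without bisulfite conversion.
    Mechanochemical DNA fragmentation during library preparation is
    sequence-dependent and is enhanced at methylated CpG dinucleotides, so the
    distribution of read 5'-end coordinates carries a methylation signal. The
    package extracts strand-aware break dinucleotides from read starts,
    summarises each island as a 16-dimensional vector of dinucleotide
    fragmentation odds ratios, labels islands from WGBS methylomes, trains a
    random-forest classifier with a top-r posterior ranking rule, and ships a
    fragmentation simulator so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    IRanges,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
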