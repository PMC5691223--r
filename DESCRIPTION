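Package: spiscan
Title: Annotation and Characterization of Serine Protease Inhibitor Genes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: A tidyverse-native pipeline for genome-wide annotation of serine
    protease inhibitor (SPI) proteins in insects.  Detects the seven common
    SPI domain families (serpin, Kazal, Pacifastin, TIL, Kunitz/BPTI, WAP and
    alpha-2-macroglobulin) on raw protein sequences using cysteine-framework
    spacing patterns and motif rules; annotates serpin reactive-center loops
    and P1 scissile residues with protease-class specificity calls; maps
    canonical-inhibitor disulfide connectivity; predicts dibasic cleavage of
    Pacifastin precursors; classifies thioester-containing proteins
    (A2M/iTEP); builds neighbor-joining trees with bootstrap supports; calls
    venom-gland-specific genes from FPKM matrices and computes qPCR relative
    expression by the 2^-ddCt method.  Ground-truthed synthetic data
    generators make every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
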