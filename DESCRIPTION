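Package: landgen
Title: Comparative Genomic Landscapes, Introgression and Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Window-based comparative population genomics for multispecies
    whole-genome resequencing data. Computes diversity and divergence
    statistics (nucleotide diversity, Watterson's theta, Tajima's D, FST,
    dXY, net divergence) in non-overlapping genomic windows; performs
    trio-based introgression inference (Patterson's D with block-jackknife
    significance, f4-admixture ratio, f-branch, windowed fd/fdM, and a
    calibrated top-X% region caller); runs haplotype-based selection scans
    (H12, nSL) and derived deleterious-allele burden accounting under
    additive and recessive models; and summarizes landscape structure
    across species with PCA, rank correlations, Mantel tree concordance,
    permutation autocorrelation, phylogenetic contrasts and
    correlation-versus-divergence dynamics. A bundled multispecies
    coalescent simulator with admixture pulses and full ground truth
    supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
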