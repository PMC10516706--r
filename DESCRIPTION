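Package: somaticsim
Title: Stochastic Simulation of Tumour-Normal Sequencing Data with a
    Comprehensive Truth Set
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates matched tumour/normal short-read sequencing data from
    a personalized phased diploid genome in which every non-reference base
    has a recorded source (germline variant, somatic spike-in, DNA-damage
    artefact or sequencing error).  Somatic single-nucleotide variants are
    spiked into reads stochastically (per-fragment Bernoulli sampling on one
    haplotype, so alternate-allele read counts are binomial random
    variables) or deterministically (read-fraction editing, emulating
    BAMSurgeon-style tools).  Ground-truth allele-frequency spectra follow a
    neutral-evolution 1/f model, a low-frequency point mass, or uniform
    semi-centile bins.  Formalin-fixation (C>T) and oxidative 8-oxoG (G>T)
    damage artefacts are injected with trinucleotide-context matching from
    96-channel single-base-substitution signatures and strand-orientation
    purity.  An evaluation layer scores any somatic caller's VCF against the
    comprehensive truth set: detection-rate matrices over semi-centile bins,
    filter attribution, false-negative causes, allele-frequency bias, tumour
    mutation burden and strand-evidence contingency analysis, together with
    a minimal tumour-normal binomial caller used as an internal surrogate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    vcfR,
    yaml,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
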