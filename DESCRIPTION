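Package: beatcall
Title: Cardiac Rhythm Quantification and Allele-Specific CRISPR Dosage
    Screening in Zebrafish Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image- and amplicon-based phenotype/genotype screening
    of zebrafish embryos. Quantifies heart rate, heart-rate variability (SDNN,
    RMSSD and their composite) and sinoatrial pause/arrest events from frame
    stacks of the beating atrium via template correlation and peak detection;
    calls CRISPR/Cas9-induced variants allele-specifically from deep amplicon
    reads with a global affine-gap aligner and haplotype clustering, annotates
    coding consequences and converts them to impact-weighted dosage scores;
    fits mutually adjusted additive and two-versus-zero association models
    with rank-based inverse-normal transforms and Hardy-Weinberg checks; and
    computes efficiency-corrected relative expression by the Pfaffl method.
    Includes synthetic-data generators (pulsating-ellipse recordings with known
    beat schedules, diploid amplicon read sets with injected edits) so every
    stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    tiff,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
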