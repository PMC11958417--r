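Package: mhcseg
Title: Pedigree-Based Haplotype Phasing and Diversity of MHC II Beta Amplicon Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the segregation of multigene-family MHC class II
    beta alleles in families of the small-spotted catshark and similar systems
    with co-amplifying allelic lineages. Implements post-denoising filtering and
    artifact classification of amplicon sequence variant (ASV) tables,
    lineage assignment of alleles from reference panels, likelihood-ratio (LOD)
    parentage from co-dominant microsatellites, exhaustive pedigree-based
    haplotype phasing with recombinant and hemizygosity inference, haplotype
    cataloguing with genetic-architecture checks, and within-haplotype sequence
    and Grantham functional diversity. A seeded simulator generates allele
    pools, pedigrees with multiple paternity, noisy read tables and
    microsatellite genotypes with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
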