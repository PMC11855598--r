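Package: clonesort
Title: Clonal Evolution Analysis of Flow-Sorted Tumor Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs tumor clonal evolution from flow-sorted tumor
    populations profiled by whole-exome sequencing. Provides ploidy and purity
    estimation from DNA-content (DAPI) flow cytometry, a somatic variant
    filtering cascade with panel-of-normals exclusion, closed-form cancer cell
    fraction (CCF) estimation with multiplicity and clonality calls,
    multi-sample CCF clustering by a seeded binomial-mixture EM, clone-tree
    construction and metastasis-seeding inference, maximum-parsimony
    phylogenies from binary mutation matrices, mutational-signature refitting
    against a COSMIC-format reference, and copy-number concordance analysis.
    A synthetic-data generator emulates polygenomic tumors and FACS sorting so
    the full pipeline can be exercised with complete ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    phangorn,
    pracma,
    mclust
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
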