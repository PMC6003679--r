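Package: radmixr
Title: RAD-Seq Locus Filtering, Introgression Tests, Quartet Species
    Trees, and Coalescent Unit Conversion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reduced-representation (RAD/GBS) phylogenomics at
    the species boundary: locus- and site-level filtering of short-read
    loci (SNP-excess, shared-heterozygosity paralog, coverage-tier and
    per-taxon coverage filters), extraction of biallelic SNP matrices
    with a per-locus index, pooled-frequency ABBA-BABA D-statistics with
    nonparametric locus-bootstrap Z-scores, exhaustive quartet inference
    by SVD scoring of site-pattern flattenings with max-cut supertree
    amalgamation and bootstrap support, summarization of replicate
    Bayesian clustering runs (convergence filtering, label alignment,
    Evanno delta-K), conversion of multispecies-coalescent tau/theta
    posteriors to geological time and effective population size under
    gamma rate priors, and a multispecies-coalescent simulator with
    admixture pulses for end-to-end validation on data with known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
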