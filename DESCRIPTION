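Package: cnmed
Title: Minimum-Event Distances and Whole-Genome-Doubling-Aware Phylogenies
    from Allele-Specific Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the minimum-event distance (MED) between segmented
    haplotype-specific integer copy-number profiles using a weighted
    finite-state transducer formulation over the tropical semiring, with
    optional whole-genome doubling (WGD) events.  Provides evolutionary
    phasing of major/minor copy numbers, pairwise distance matrices with a
    prime-grid parallel schedule, neighbor-joining tree inference rooted at
    a diploid reference, minimum-event ancestral genome reconstruction,
    per-branch event extraction, WGD evidence scoring with bootstrap
    support, chromosome-bootstrap and segment-jackknife resampling, and two
    simulators of tumor copy-number evolution for validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
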