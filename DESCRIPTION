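Package: asymtopo
Title: Topological Analysis of Hemispheric Brain Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures structural brain asymmetry with cubical persistent
    homology and relates it to behavior. From voxel-wise flip-subtracted
    asymmetry volumes it computes 2-cycle (cavity) persistence diagrams per
    region of interest and per hemisphere, transforms them into first
    persistence landscapes on a fixed position grid, and tests two hypotheses
    position-by-position: a linear association between maximal asymmetry and a
    standardized behavioral score (cerebral lateralization), and an inverted-U
    upper-envelope association via 99th-percentile quadratic quantile
    regression (canalization). Inference pools chained-equations imputations
    and bootstrap resamples, corrects family-wise error with a permutation
    run-length extent threshold across landscape positions, and applies a
    two-sample replication gate. A synthetic-cohort generator produces
    asymmetry volumes, parcellations and behavioral tables with known
    topological and statistical ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    quantreg,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
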