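Package: slicewise
Title: Spatial Protein Profiles and Distance-Delay Networks from Serial Tissue Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns wide protein-group quantification matrices from serial
    tissue cryosections (e.g. DIA-NN output for sequential 20 um muscle
    sections) into normalized, imputed, replicate-aligned spatial protein
    profiles, and infers a directed distance-delay protein network with
    data-processing-inequality pruning. Includes robust generalized-log
    normalization with per-slice input correction, sliding-window
    missingness filtering, distance-weighted linear imputation with a
    downshifted-normal fallback, a quantitative trend statistic with a
    permutation null for marker selection, loess-based replicate axis
    alignment, delay cross-correlation network construction, a synthetic
    serial-section data generator with recorded ground truth, and
    protocol-planning helpers (section counts, iRT peptide m/z).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
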