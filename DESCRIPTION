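Package: metaboplot
Title: Processing, Isotope Correction and Per-Metabolite Plotting of
    Quantified Metabolomics Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns quantified compound-intensity tables from targeted
    metabolomics and stable-isotope tracing experiments into tidy long
    tables, publication-style per-metabolite plots and structured result
    exports.  Reads five common table dialects (TraceFinder-style lists,
    Compound Discoverer matrices, compounds-in-columns, generic list and
    generic matrix layouts), annotates samples from a design table,
    performs external (cell count / protein), internal-standard and
    total-peak-sum normalisation, quality-controls replicates via
    fold-change centering, parses isotopologue-labelled compound names,
    and corrects mass-isotopomer distributions for natural isotope
    abundance and tracer purity by non-negative least squares.  Results
    are rendered with ggplot2 (bar, scatter, violin, box, replicate and
    stacked-isotopologue plots) and bundled into a reproducible zip
    archive.
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
    grDevices,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    zip
Suggests:
    xml2,
    jsonlite,
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
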