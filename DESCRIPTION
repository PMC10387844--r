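Package: ftirquant
Title: Macromolecular Quantification of Cell FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies macromolecular composition of cultured cells from
    Fourier-transform infrared (FTIR) absorbance spectra. Implements
    two-point linear baseline correction of analysis regions, reference-band
    normalization, apex intensity and sub-resolution band position
    measurement by parabolic refinement, and the derived macromolecular
    indices used in cell biospectroscopy (lipid-to-protein ratio, acyl chain
    length, olefinic lipid-peroxidation band, glycogen, RNA and phosphate
    bands), with replicate-group comparison by the exact Mann-Whitney U test
    or the unpaired t-test. Also provides a differential-expression
    concordance procedure for paired DE result tables (shared significant
    genes, direction-parallel counts, Pearson correlation of fold changes),
    and a seeded synthetic-data generator for spectra and DE tables with
    planted, recoverable structure.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
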