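Package: ilqsar
Title: QSAR Modeling of Ionic Liquids Under Separate-Ion and Ionic-Pair
    Structure Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking how the representation of ionic-liquid
    structure affects QSAR model quality. Computes 2D topological descriptors
    (Gutman molecular topological index, mean distance degree deviation,
    Schultz MTI by valence vertex degrees, intrinsic-state pseudoconnectivity,
    average molecular weight) from hydrogen-depleted molecular graphs parsed
    from SMILES, assembles ionic-liquid descriptor matrices under the
    separate-ion (A|B) and ionic-pair ([A+B], additive) representations,
    merges externally computed descriptor tables, fits stepwise multiple
    linear regression models, and evaluates them with a full internal/external
    validation battery (leave-one-out Q2, external Q2, concordance correlation
    coefficient, modified r2, Golbraikh-Tropsha checklist, Toth F-test) and
    applicability-domain assessment (Roy standardization approach and
    leverage/Williams analysis). Includes a synthetic ionic-liquid data
    generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
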