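Package: mifilter
Title: Mono- and Intralink Filtering of Cross-Linking Mass Spectrometry Identifications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for post-search filtering of cross-linking mass
    spectrometry (XL-MS) identification tables. Implements the mono-/intralink
    ("mi") filter, which retains an inter-protein cross-link only when both
    partner proteins carry at least one monolink or intra-protein cross-link
    in the same dataset; parses xQuest-dialect TSV exports and a generic CSV
    schema; performs per-link-class target/decoy accounting across ld-score
    cutoffs before and after filtering; applies a biological-replicate
    consistency filter on cross-linking sites; validates retained
    inter-protein links against 3D structures by minimal C-alpha--C-alpha
    distance; exports xiNET-compatible network edge lists; and simulates
    synthetic XL-MS datasets with ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
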