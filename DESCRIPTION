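Package: modbp
Title: Annotation, Atlas and Energetics of Modified RNA Base Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and classifies hydrogen-bonded RNA base pairs that involve
    posttranscriptionally modified nucleobases in 3D structures, using an
    extended Leontis-Westhof nomenclature with flags for ribose 2'-OH
    involvement, bridging waters, bifurcated contacts and single-H-bond pairs.
    Aggregates annotations into an occurrence atlas with best-resolution
    representatives, builds capped quantum-chemistry-ready model fragments of
    base pairs together with their unmodified counterparts, performs
    least-squares superposition with explicit atom correspondences (including
    the structural pseudouridine ring map), and implements the bookkeeping of
    counterpoise-corrected interaction energies and modification energies.
    A synthetic-structure generator produces idealized base pairs for every
    atlas pair type for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
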