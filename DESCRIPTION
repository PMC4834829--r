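Package: patternsim
Title: Ligand-Independent Comparison of Three-Dimensional Residue Patterns
    in Protein Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free, ligand-independent detection and pairwise
    comparison of three-dimensional residue patterns in protein structures.
    Builds a virtual grid of reference coordinates from midpoints of nearby
    side-chain geometric centers, grows one candidate pattern per grid
    point under near/far distance thresholds, describes each pattern with
    four sequence-order-independent descriptors (inter-residue distance
    tokens, summed non-bonded energy, physicochemical sequence component,
    and a travelling-salesman perimeter), and scores every cross-structure
    pattern pair with a weighted similarity (GScore). Includes a synthetic
    PDB fixture generator with exactly planted side-chain centers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
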