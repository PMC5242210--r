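Package: asbscaffold
Title: Analog Series-Based Scaffolds from Matched Molecular Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts analog series from bioactive compound collections and
    isolates analog series-based (ASB) scaffolds. Activity records are
    curated to high-confidence human-target data with geometric-mean potency
    aggregation, compounds are fragmented at retrosynthetic (RECAP) bonds,
    size-constrained matched molecular pairs (MMPs) are generated by core
    indexing, analog series are taken as connected components of the MMP
    network, structural key (SK) compounds are identified, and the largest
    MMP core of an SK compound covering all analog relationships of a series
    is reported as its ASB scaffold; where no single core qualifies, a
    minimum core cover is computed. Includes a seeded synthetic fixture
    generator with ground truth for end-to-end validation. Structure-level
    primitives (SMILES canonicalization, substructure matching, bond
    fragmentation) are delegated to a bundled RDKit helper script run
    through a system Python interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python' (override with option asbscaffold.python or env ASB_PYTHON)
Config/testthat/edition: 3
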