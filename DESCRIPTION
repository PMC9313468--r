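Package: fodm
Title: Fuzzy Oil Drop Analysis of Hydrophobicity Distributions in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how closely the hydrophobicity distribution of a protein
    structure follows the centric, micelle-like organisation expected of a
    water-soluble globule, and how strongly a membrane-like environment has
    reshaped it. Implements the fuzzy-oil-drop (FOD) model -- a theoretical
    per-residue distribution from a 3D Gaussian fitted to the molecule, an
    observed distribution aggregated from pairwise inter-residue hydrophobic
    interactions, and a uniform reference -- together with its membrane-modified
    extension (FOD-M) in which the Gaussian is blended with its normalised
    inversion weighted by a coefficient K. Divergence statistics (Kullback-Leibler
    divergence, the relative distance RD, the optimal K) score whole complexes,
    single chains, fragments, interface residues, ligand-contact residues,
    disulfide-delimited segments, membrane zones and beta-sheet strands.
    Includes seeded generators for synthetic globular and channel-like test
    structures, and a pipeline for paired comparative runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    bio3d,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'benchmark.R'
    'divergence.R'
    'field.R'
    'fodm-package.R'
    'partition.R'
    'pipeline.R'
    'scales.R'
    'structure.R'
    'subsets-io.R'
    'synthetic.R'
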