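Package: thermbond
Title: Quantifying Hydrogen Bonds, Salt Bridges, and Amino-Acid Use Across
    Protein Structure Sets
Version: 0.1.0
Authors@R:
    person("Structural", "Bioinformatics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-throughput quantification of stabilizing non-covalent
    interactions in protein structure models, for detecting signatures of
    protein temperature adaptation between species. Enumerates hydrogen
    bonds under distance-only donor/acceptor criteria (3.5 A heavy-atom,
    2.5 A hydrogen-acceptor) and salt bridges (Asp/Glu carboxyl oxygen
    within 4.0 A of an Arg/Lys/His side-chain nitrogen) in PDB-format
    models, builds per-protein feature tables normalized by sequence
    length, applies model-quality and annotation filters, and runs the
    comparative statistics used in proteome-scale temperature-adaptation
    studies: Mann-Whitney U comparisons of full sets, ortholog pairs and
    upper quantiles, chi-square tests of amino-acid use, Spearman
    correlations against residue hydrophobicity and volume ranks, and
    per-term Fisher exact over-representation of GO annotations. A
    synthetic-data module generates ideal helices, salt-bridge dimers and
    two-species proteome ensembles with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
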