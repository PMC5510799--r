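Package: metabograph
Title: Integrated Biochemical Knowledge Graphs with Reaction Balancing
    and Pathway Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a typed, labelled property graph of biochemical
    knowledge (organisms, enzymes, reactions, chemicals) from flat-file
    exports in the dialects of the NCBI Taxonomy, MNXref, ChEBI and
    UniProt resources. Cross-references are normalised to identifiers.org
    namespaces and entities appearing in several sources are merged by
    shared accessions, so that each chemical species occurs once while
    retaining its ontology and reaction-network context. Reactions are
    mass- and charge-balanced by a minimal-perturbation integer search
    that can restore commonly missing species such as protons and water,
    and reaction participants are classified as reactants or cofactors
    (low molecular mass, or frequently co-occurring opposite-sign pairs
    such as ATP/ADP). Query operations cover reaction-in-organism
    context, chemical-ontology descendants, taxon-restricted metabolome
    windows, stoichiometry-directed shortest pathway search between a
    host metabolite and a target molecule, and enzyme/organism lookup
    along pathways. Graphs round-trip through a bulk-import CSV dialect
    compatible with property-graph batch loaders, and a deterministic
    synthetic fixture generator provides ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
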