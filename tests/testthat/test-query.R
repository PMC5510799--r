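test_that("reaction context returns the organism-linked neighbourhood", {
  g <- hexokinase_demo_graph()
  sg <- reaction_context(g, c("kegg.reaction", "R00299"), "83333")
  expect_gt(nrow(sg$nodes), 0L)
  expect_equal(subgraph_edge_count(sg, "has_reactant"), 2L)
  expect_equal(subgraph_edge_count(sg, "has_cofactor"), 2L)
  enz <- sg$nodes$key[sg$nodes$label == "Enzyme"]
  expect_equal(get_node(g, "Enzyme", enz)$name, "Glucokinase")
  # the organism and its is_a parent are present
  orgs <- sg$nodes$key[sg$nodes$label == "Organism"]
  expect_setequal(orgs, c("83333", "562"))
  # chemical-chemical edge among returned chemicals
  expect_equal(subgraph_edge_count(sg, "has_functional_parent"), 1L)
})

test_that("reaction context is empty without a linking enzyme", {
  g <- hexokinase_demo_graph()
  # taxon exists but expresses nothing
  expect_equal(nrow(reaction_context(g, c("kegg.reaction", "R00299"),
                                     "562")$nodes), 0L)
  expect_equal(nrow(reaction_context(g, c("kegg.reaction", "R99999"),
                                     "83333")$nodes), 0L)
  expect_equal(nrow(reaction_context(g, c("kegg.reaction", "R00299"),
                                     "404")$nodes), 0L)
})

ontology_chain <- function() {
  g <- kgraph()
  upsert_node(g, "Chemical", chemical_entity("FLAV", name = "flavonoid"))
  upsert_node(g, "Chemical", chemical_entity("FLNE", name = "flavone"))
  upsert_node(g, "Chemical", chemical_entity(
    "APIG", name = "apigenin", formula = "C15H10O5",
    xrefs = c(chebi = "CHEBI:18388")))
  add_relationship(g, relationship("Chemical", "FLNE", "is_a",
                                   "Chemical", "FLAV"))
  add_relationship(g, relationship("Chemical", "APIG", "is_a",
                                   "Chemical", "FLNE"))
  g
}

test_that("descendants close transitively and filter on formula", {
  g <- ontology_chain()
  rows <- descendant_chemicals(g, "flavonoid", require_formula = TRUE)
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$name, "apigenin")
  expect_equal(rows$chebi, "CHEBI:18388")
  expect_equal(nrow(descendant_chemicals(g, "flavonoid", FALSE)), 2L)
  # injected cycle terminates with each node visited once
  add_relationship(g, relationship("Chemical", "FLAV", "is_a",
                                   "Chemical", "APIG"))
  rows2 <- descendant_chemicals(g, "flavonoid", FALSE)
  expect_equal(nrow(rows2), 2L)
})

test_that("descendants equal the matrix-power transitive closure", {
  fl <- synthetic_flavonoid_ontology(n_with_formula = 60, n_classes = 12,
                                     seed = 6)
  rows <- descendant_chemicals(fl, "flavonoid", require_formula = FALSE)
  roots <- attr(rows, "roots")
  want <- oracle_descendant_keys(fl, roots)
  got_names <- sort(rows$name)
  want_names <- sort(vapply(want, function(k)
    get_node(fl, "Chemical", k)$name, character(1), USE.NAMES = FALSE))
  expect_equal(got_names, want_names)
})

test_that("taxon metabolome applies strict bounds and excludes cofactors", {
  mb <- synthetic_strain_metabolome(n_in_range = 9, n_below = 3,
                                    n_above = 3, n_cofactor_decoys = 2,
                                    seed = 3)
  rows <- taxon_metabolome(mb, "562", 400, 500)
  expect_equal(nrow(rows), 9L)
  # boundary masses at exactly 400 and 500 are excluded (strict bounds)
  expect_true(all(rows$monoisotopic_mass > 400 &
                    rows$monoisotopic_mass < 500))
  # cofactor-linked chemicals never appear
  expect_false(any(grepl("^cofactor decoy", rows$name)))
  expect_equal(nrow(taxon_metabolome(mb, "562", 400, 400.1)), 0L)
  expect_error(taxon_metabolome(mb, "562", 500, 400),
               class = "kg_validation_error")
  # monotonicity: a wider window never shrinks the result
  narrow <- taxon_metabolome(mb, "562", 420, 470)
  wide <- taxon_metabolome(mb, "562", 400, 500)
  expect_true(all(narrow$name %in% wide$name))
})

test_that("pathways follow the stoichiometry sign rule", {
  g <- pathway_chain_graph()
  paths <- find_pathways(g, "9", "T")
  expect_length(paths, 1L)
  expect_equal(pathway_node_sequence(paths[[1]]),
               c("S", "r1", "M", "r2", "T"))
  expect_equal(paths[[1]]$length, 2L)
  expect_true(validate_pathway(paths[[1]]))
  # breaking the signs at M leaves no valid pathway
  expect_length(find_pathways(pathway_chain_graph(break_signs = TRUE),
                              "9", "T"), 0L)
  # a native target yields a single length-0 pathway
  p0 <- find_pathways(g, "9", "S")
  expect_length(p0, 1L)
  expect_equal(p0[[1]]$length, 0L)
  expect_error(find_pathways(g, "9", "NOPE"),
               class = "kg_validation_error")
})

test_that("pathway search equals brute-force enumeration", {
  for (seed in 0:9) {
    rg <- random_reaction_graph(20, 20, seed = seed)
    got <- find_pathways(rg$graph, rg$host, rg$target, max_len = 8)
    got_keys <- sort(vapply(got, function(p)
      paste(pathway_node_sequence(p), collapse = "\r"), character(1)))
    want <- oracle_pathways(rg$graph, rg$host, rg$target, max_len = 8)
    expect_equal(got_keys, want, info = seed)
    for (p in got) expect_true(validate_pathway(p))
  }
})

test_that("pathway enzymes report all catalyst/organism pairs", {
  g <- pathway_chain_graph()
  # two donor organisms (not the host) express an enzyme for r2
  upsert_node(g, "Enzyme", enzyme_entity("E2", name = "donor enzyme"))
  upsert_node(g, "Enzyme", enzyme_entity("E3", name = "orphan enzyme"))
  for (org in c("10", "11")) {
    upsert_node(g, "Organism", organism_entity(
      org, name = paste("donor", org), parent_taxonomy = "9"))
    add_relationship(g, relationship("Organism", org, "is_a",
                                     "Organism", "9"))
    add_relationship(g, relationship("Organism", org, "expresses",
                                     "Enzyme", "E2"))
  }
  add_relationship(g, relationship("Reaction", "r2", "catalysed_by",
                                   "Enzyme", "E2"))
  add_relationship(g, relationship("Reaction", "r1", "catalysed_by",
                                   "Enzyme", "E3"))
  paths <- find_pathways(g, "9", "T")
  rows <- pathway_enzymes(g, paths)
  r2 <- rows[rows$reaction_id == "r2", ]
  expect_equal(nrow(r2), 2L)              # one per expressing organism
  expect_setequal(r2$organism_taxonomy, c("10", "11"))
  r1 <- rows[rows$reaction_id == "r1", ]  # enzyme without organism
  expect_equal(r1$enzyme_id, "E3")
  expect_equal(r1$organism_taxonomy, "")
  expect_equal(nrow(pathway_enzymes(g, list())), 0L)
})
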