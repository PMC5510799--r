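test_that("upsert is idempotent and merges properties", {
  g <- kgraph()
  upsert_node(g, "Chemical", chemical_entity("CHEBI:17234",
                                             name = "glucose"))
  upsert_node(g, "Chemical", chemical_entity("CHEBI:17234",
                                             name = "glucose"))
  expect_equal(node_count(g, "Chemical"), 1L)
  # second upsert fills missing fields and unions lists
  upsert_node(g, "Chemical", chemical_entity(
    "CHEBI:17234", name = "dextrose", names = "grape sugar",
    formula = "C6H12O6"))
  chem <- get_node(g, "Chemical", "CHEBI:17234")
  expect_equal(chem$name, "glucose")          # first-loaded name wins
  expect_true(all(c("dextrose", "grape sugar") %in% chem$names))
  expect_equal(chem$formula, "C6H12O6")
})

test_that("upsert rejects bad input", {
  g <- kgraph()
  expect_error(upsert_node(g, "Chemical", list(id = "X", formula = "XYZ123!")),
               class = "kg_validation_error")
  expect_error(upsert_node(g, "Protein", list(id = "X")),
               class = "kg_schema_error")
  expect_error(upsert_node(g, "Chemical", list(name = "no key")),
               class = "kg_error")
})

test_that("relationships enforce endpoints and signatures, and dedupe", {
  g <- kgraph()
  upsert_node(g, "Organism", organism_entity("83333", name = "K-12"))
  upsert_node(g, "Enzyme", enzyme_entity("P0A6V8", name = "Glucokinase"))
  # dangling endpoint
  expect_error(add_relationship(g, relationship(
    "Organism", "83333", "is_a", "Organism", "562")),
    class = "kg_validation_error")
  # expresses edge with source property
  add_relationship(g, relationship("Organism", "83333", "expresses",
                                   "Enzyme", "P0A6V8",
                                   properties = list(source = "uniprot")))
  expect_equal(relationship_count(g), 1L)
  # wrong direction for the type signature
  expect_error(add_relationship(g, relationship(
    "Enzyme", "P0A6V8", "expresses", "Organism", "83333")),
    class = "kg_schema_error")
  upsert_node(g, "Reaction", reaction_entity("R1"))
  expect_error(add_relationship(g, relationship(
    "Reaction", "R1", "has_reactant", "Organism", "83333")),
    class = "kg_schema_error")
  # identical duplicates collapse; differing source kept as provenance
  add_relationship(g, relationship("Organism", "83333", "expresses",
                                   "Enzyme", "P0A6V8",
                                   properties = list(source = "uniprot")))
  expect_equal(relationship_count(g), 1L)
  add_relationship(g, relationship("Organism", "83333", "expresses",
                                   "Enzyme", "P0A6V8",
                                   properties = list(source = "kegg")))
  expect_equal(relationship_count(g), 2L)
})

test_that("summary_stats coverage matches the taxonomy-chain hand count", {
  g <- organism_chain(4)
  st <- summary_stats(g)
  row <- st$relationships[st$relationships$from_label == "Organism" &
                            st$relationships$to_label == "Organism", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$n_nodes_with, 3L)   # the root has no is_a edge out
  expect_equal(row$coverage_pct, 75)
})

test_that("summary_stats on an empty graph is empty", {
  st <- summary_stats(kgraph())
  expect_equal(nrow(st$nodes), 0L)
  expect_equal(nrow(st$relationships), 0L)
})

test_that("summary_stats reports both orientations and full coverage", {
  truth <- generate_fixture(fixture_spec(seed = 5), fx_dir <- tempfile())
  g <- suppressWarnings(build_graph(fx_dir))$graph
  st <- summary_stats(g)$relationships
  # every enzyme is linked to >= 1 reaction: Enzyme-Reaction coverage 100
  er <- st[st$from_label == "Enzyme" & st$to_label == "Reaction", ]
  expect_equal(er$coverage_pct, 100)
  # the reverse orientation is reported too
  re <- st[st$from_label == "Reaction" & st$to_label == "Enzyme", ]
  expect_equal(nrow(re), 1L)
  unlink(fx_dir, recursive = TRUE)
})

test_that("summary_stats equals a brute-force per-node scan", {
  rg <- random_reaction_graph(15, 15, seed = 3)
  st <- summary_stats(rg$graph)$relationships
  rels <- graph_relationships(rg$graph)
  for (i in seq_len(nrow(st))) {
    a <- st$from_label[i]; b <- st$to_label[i]
    keys <- graph_nodes(rg$graph, a)
    has <- vapply(keys, function(k) {
      out <- any(rels$from_label == a & rels$from_id == k &
                   rels$to_label == b)
      inc <- if (a != b) any(rels$to_label == a & rels$to_id == k &
                               rels$from_label == b) else FALSE
      out || inc
    }, logical(1))
    expect_equal(st$n_nodes_with[i], sum(has))
    expect_equal(st$coverage_pct[i], 100 * sum(has) / length(keys))
  }
})

test_that("validate_graph checks referential integrity and tree shape", {
  g <- organism_chain(3)
  expect_true(validate_graph(g))
  # second root
  upsert_node(g, "Organism", organism_entity("99", name = "stray root"))
  expect_error(validate_graph(g), class = "kg_validation_error")
})
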