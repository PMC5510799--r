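# Small graph builders shared across test files.

# Chemicals of the hexokinase reaction with full formulas/charges.
hexokinase_chemicals <- function() {
  list(
    glc = chemical_entity("glc", name = "D-glucopyranose",
                          formula = "C6H12O6", charge = 0L),
    atp = chemical_entity("atp", name = "ATP(4-)",
                          formula = "C10H12N5O13P3", charge = -4L),
    g6p = chemical_entity("g6p", name = "D-glucopyranose 6-phosphate",
                          formula = "C6H11O9P", charge = -2L),
    adp = chemical_entity("adp", name = "ADP(3-)",
                          formula = "C10H12N5O10P2", charge = -3L),
    "H+" = chemical_entity("H+", name = "proton", formula = "H",
                           charge = 1L),
    H2O = chemical_entity("H2O", name = "water", formula = "H2O",
                          charge = 0L))
}

hexokinase_participants <- function(with_proton = TRUE) {
  ids <- c("glc", "atp", "g6p", "adp", if (with_proton) "H+")
  data.frame(chemical_id = ids,
             stoichiometry = c(-1L, -1L, 1L, 1L, if (with_proton) 1L),
             role = "reactant", stringsAsFactors = FALSE)
}

# A linear chain of organisms 1 <- 2 <- ... <- n (is_a child -> parent).
organism_chain <- function(n) {
  g <- kgraph()
  ids <- as.character(seq_len(n))
  upsert_node(g, "Organism", organism_entity(ids[1], name = "root"))
  for (i in seq_len(n)[-1]) {
    upsert_node(g, "Organism", organism_entity(
      ids[i], name = paste("taxon", i), parent_taxonomy = ids[i - 1]))
    add_relationship(g, relationship("Organism", ids[i], "is_a",
                                     "Organism", ids[i - 1]))
  }
  g
}

# Host-wired chemical/reaction chain: r0 produces S from X (host
# catalysed), then S -r1-> M -r2-> T with correct signs. Only r0 is
# catalysed by the host's enzyme, so the native set is {X, S}.
pathway_chain_graph <- function(break_signs = FALSE) {
  g <- kgraph()
  for (id in c("X", "S", "M", "T"))
    upsert_node(g, "Chemical", chemical_entity(id, name = id))
  upsert_node(g, "Organism", organism_entity("9", name = "host"))
  upsert_node(g, "Enzyme", enzyme_entity("E1", name = "host enzyme"))
  add_relationship(g, relationship("Organism", "9", "expresses",
                                   "Enzyme", "E1",
                                   properties = list(source = "uniprot")))
  for (r in c("r0", "r1", "r2"))
    upsert_node(g, "Reaction", reaction_entity(r))
  add_relationship(g, relationship("Reaction", "r0", "catalysed_by",
                                   "Enzyme", "E1",
                                   properties = list(source = "kegg")))
  edge <- function(r, c, s)
    add_relationship(g, relationship(
      "Reaction", r, "has_reactant", "Chemical", c,
      properties = list(stoichiometry = s)))
  edge("r0", "X", -1L); edge("r0", "S", 1L)
  edge("r1", "S", -1L); edge("r1", "M", 1L)
  if (break_signs) {
    edge("r2", "M", 1L); edge("r2", "T", 2L)   # M produced twice: invalid
  } else {
    edge("r2", "M", -1L); edge("r2", "T", 1L)
  }
  g
}
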