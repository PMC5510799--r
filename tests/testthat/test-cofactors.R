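test_that("low-mass classification uses strict 44 Da on available mass", {
  water <- chemical_entity("w", formula = "H2O", charge = 0L)
  expect_true(is_low_mass_cofactor(water))          # 18.0106 Da
  atp <- chemical_entity("atp", formula = "C10H12N5O13P3", charge = -4L,
                         monoisotopic_mass = 506.9957)
  expect_false(is_low_mass_cofactor(atp))
  proton <- chemical_entity("h", formula = "H", charge = 1L)
  expect_true(is_low_mass_cofactor(proton))         # 1.0078 Da
  co2 <- chemical_entity("c", formula = "CO2", charge = 0L)
  expect_true(is_low_mass_cofactor(co2))            # 43.9898 < 44, strictly
  class_node <- chemical_entity("fatty acid", name = "fatty acid")
  expect_false(is_low_mass_cofactor(class_node))    # no mass, no formula
  # monotone in mass: anything lighter than a cofactor is one too
  masses <- c(1, 17.5, 43.9, 44, 44.0001, 180)
  flags <- vapply(masses, function(m)
    is_low_mass_cofactor(chemical_entity("x", monoisotopic_mass = m)),
    logical(1))
  expect_equal(flags, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

toy_reactions <- function() {
  mk <- function(id, neg, pos) reaction_entity(
    id, participants = data.frame(
      chemical_id = c(neg, pos),
      stoichiometry = c(rep(-1L, length(neg)), rep(1L, length(pos))),
      role = "reactant", stringsAsFactors = FALSE))
  list(mk("r1", c("glc", "atp"), c("g6p", "adp")),
       mk("r2", c("fru", "atp"), c("f6p", "adp")),
       mk("r3", c("gol", "atp"), c("g3p", "adp")))
}

test_that("frequent pairs require opposite signs at the threshold", {
  pairs <- detect_frequent_pairs(toy_reactions(), min_pair_count = 2)
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$a, pairs$b), c("adp", "atp"))
  expect_equal(pairs$n_reactions, 3L)
  expect_equal(nrow(detect_frequent_pairs(toy_reactions(), 4)), 0L)
  # a pair co-occurring on the same side only never counts
  same_side <- list(reaction_entity("s1", participants = data.frame(
    chemical_id = c("a", "b", "c"), stoichiometry = c(-1L, -1L, 1L),
    role = "reactant")), reaction_entity("s2", participants = data.frame(
      chemical_id = c("a", "b", "d"), stoichiometry = c(-1L, -1L, 1L),
      role = "reactant")))
  got <- detect_frequent_pairs(same_side, 2)
  expect_false(any(got$a == "a" & got$b == "b"))
  expect_error(detect_frequent_pairs(toy_reactions(), 1),
               class = "kg_validation_error")
})

test_that("frequent-pair detection agrees with an exhaustive census", {
  set.seed(21)
  chems <- sprintf("c%02d", 1:10)
  rxns <- lapply(1:20, function(i) {
    k <- sample(2:4, 1)
    ids <- sample(chems, k)
    st <- c(-1L, 1L, sample(c(-1L, 1L), k - 2, replace = TRUE))
    reaction_entity(sprintf("r%02d", i), participants = data.frame(
      chemical_id = ids, stoichiometry = st, role = "reactant",
      stringsAsFactors = FALSE))
  })
  for (mpc in 2:4) {
    got <- detect_frequent_pairs(rxns, mpc)
    expect_equal(sort(paste(got$a, got$b, sep = "|")),
                 oracle_frequent_pairs(rxns, mpc), info = mpc)
  }
})

test_that("cofactor annotation relabels edges but conserves structure", {
  g <- hexokinase_demo_graph()
  rels <- graph_relationships(g)
  rc <- rels[rels$type %in% c("has_reactant", "has_cofactor"), ]
  expect_equal(nrow(rc), 12L)   # 3 reactions x 4 participants
  # ATP/ADP are cofactors in every reaction; substrates/products are not
  cof <- rc[rc$type == "has_cofactor", ]
  expect_setequal(unique(cof$to_id), c("CHEBI:30616", "CHEBI:456216"))
  expect_equal(nrow(cof), 6L)
  # stoichiometries survived the relabelling
  expect_equal(sort(rc$stoichiometry), sort(rep(c(-1, -1, 1, 1), 3)))
  # proton joins the cofactors via the mass rule when present
  gp <- hexokinase_demo_graph(protons = TRUE)
  rcp <- graph_relationships(gp, "has_cofactor")
  expect_true("CHEBI:15378" %in% rcp$to_id)
})

test_that("reactions without small molecules or pairs keep their edges", {
  g <- kgraph()
  for (id in c("big1", "big2"))
    upsert_node(g, "Chemical", chemical_entity(id, formula = "C20H30O10",
                                               charge = 0L))
  upsert_node(g, "Reaction", reaction_entity("r", participants =
    data.frame(chemical_id = c("big1", "big2"),
               stoichiometry = c(-1L, 1L), role = "reactant")))
  for (s in c(-1L, 1L))
    add_relationship(g, relationship(
      "Reaction", "r", "has_reactant", "Chemical",
      if (s < 0) "big1" else "big2",
      properties = list(stoichiometry = s)))
  expect_equal(annotate_cofactors(g, min_pair_count = 2), 0L)
  expect_equal(relationship_count(g, "has_cofactor"), 0L)
})
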