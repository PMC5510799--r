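test_that("entities sharing an accession merge with unioned xrefs", {
  chebi_atp <- chemical_entity("CHEBI:15422", name = "ATP",
                               xrefs = c(chebi = "CHEBI:15422",
                                         kegg.compound = "C00002"),
                               source = "chebi")
  mnx_atp <- chemical_entity("MNXM3", name = "ATP",
                             xrefs = c(mnx = "MNXM3",
                                       kegg.compound = "C00002"),
                             source = "mnxref")
  out <- merge_entities(list(mnx_atp, chebi_atp))
  expect_length(out$entities, 1L)
  atp <- out$entities[[1]]
  expect_equal(atp$id, "CHEBI:15422")   # chebi precedence wins the key
  expect_setequal(names(atp$xrefs), c("chebi", "kegg.compound", "mnx"))
  expect_equal(unname(out$report$merge_map[["MNXM3"]]), "CHEBI:15422")
})

test_that("disjoint entities stay unchanged", {
  a <- chemical_entity("A", xrefs = c(chebi = "CHEBI:1"), source = "chebi")
  b <- chemical_entity("B", xrefs = c(mnx = "MNXM2"), source = "mnxref")
  out <- merge_entities(list(a, b))
  expect_length(out$entities, 2L)
  expect_equal(nrow(out$report$conflicts), 0L)
})

test_that("merging is transitive across shared namespaces", {
  a <- chemical_entity("A", xrefs = c(chebi = "CHEBI:9"), source = "x")
  b <- chemical_entity("B", xrefs = c(chebi = "CHEBI:9", mnx = "M1"),
                       source = "y")
  c_ <- chemical_entity("C", xrefs = c(mnx = "M1"), source = "z")
  out <- merge_entities(list(a, b, c_))
  expect_length(out$entities, 1L)
  expect_setequal(names(out$report$merge_map), c("A", "B", "C"))
})

test_that("merge is idempotent and leaves no shared xrefs", {
  set.seed(11)
  ents <- lapply(1:12, function(i) {
    xr <- c(chebi = sprintf("CHEBI:%d", sample(6, 1)),
            mnx = sprintf("M%d", sample(6, 1)))
    chemical_entity(sprintf("E%02d", i), xrefs = xr,
                    source = sample(c("chebi", "mnxref"), 1))
  })
  out <- merge_entities(ents)
  # no xref value appears on two outputs
  pairs <- unlist(lapply(out$entities, function(e)
    paste(names(e$xrefs), e$xrefs, sep = ":")))
  expect_false(any(duplicated(pairs)))
  again <- merge_entities(out$entities)
  expect_length(again$entities, length(out$entities))
  expect_true(all(names(again$report$merge_map) ==
                    again$report$merge_map))
})

test_that("scalar conflicts resolve by source precedence and are logged", {
  a <- chemical_entity("CHEBI:7", formula = "C2H6O", charge = 0L,
                       xrefs = c(chebi = "CHEBI:7",
                                 kegg.compound = "C99999"),
                       source = "chebi")
  b <- chemical_entity("MNXM7", formula = "C2H7O", charge = 1L,
                       xrefs = c(mnx = "MNXM7",
                                 kegg.compound = "C99999"),
                       source = "mnxref")
  out <- merge_entities(list(b, a))
  merged <- out$entities[[1]]
  expect_equal(merged$formula, "C2H6O")   # chebi value kept
  expect_equal(merged$charge, 0L)
  conf <- out$report$conflicts
  expect_true(all(c("formula", "charge") %in% conf$property))
  expect_true(all(conf$winning_source == "chebi"))
  # contradictory accession in another shared namespace still merges
  x <- chemical_entity("X", xrefs = c(chebi = "CHEBI:8", cas = "1-11-1"),
                       source = "chebi")
  y <- chemical_entity("Y", xrefs = c(chebi = "CHEBI:8", cas = "2-22-2"),
                       source = "mnxref")
  out2 <- merge_entities(list(x, y))
  expect_length(out2$entities, 1L)
  expect_true("xref:cas" %in% out2$report$conflicts$property)
})
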