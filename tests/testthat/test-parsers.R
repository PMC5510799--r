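write_tmp <- function(lines, name) {
  path <- file.path(tempdir(), name)
  writeLines(lines, path)
  path
}

test_that("taxonomy dump parses nodes, names and is_a edges", {
  nodes <- write_tmp(c("1\t|\t1\t|\tno rank\t|",
                       "562\t|\t1\t|\tspecies\t|",
                       "83333\t|\t562\t|\tstrain\t|"), "nodes.dmp")
  names_f <- write_tmp(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "562\t|\tEscherichia coli\t|\t\t|\tscientific name\t|",
    "562\t|\tBacillus coli Migula 1895\t|\t\t|\tsynonym\t|",
    "83333\t|\tEscherichia coli K-12\t|\t\t|\tscientific name\t|"),
    "names.dmp")
  out <- parse_taxonomy_dump(nodes, names_f)
  expect_length(out$organisms, 3L)
  expect_length(out$relationships, 2L)   # no self-edge for the root
  ec <- Filter(function(o) o$taxonomy == "562", out$organisms)[[1]]
  expect_equal(ec$name, "Escherichia coli")
  expect_true("Bacillus coli Migula 1895" %in% ec$names)
  expect_false("Bacillus coli Migula 1895" == ec$name)
  root <- Filter(function(o) o$taxonomy == "1", out$organisms)[[1]]
  expect_null(root$parent_taxonomy)
})

test_that("taxonomy dump flags unknown ids and malformed lines", {
  nodes <- write_tmp("1\t|\t1\t|\tno rank\t|", "n2.dmp")
  bad_names <- write_tmp(c("1\t|\troot\t|\t\t|\tscientific name\t|",
                           "999\t|\tghost\t|\t\t|\tscientific name\t|"),
                         "m2.dmp")
  expect_warning(parse_taxonomy_dump(nodes, bad_names), "999")
  short <- write_tmp("1\t|\t1\t|", "n3.dmp")
  expect_error(parse_taxonomy_dump(short, bad_names),
               class = "kg_parse_error")
})

test_that("MNXref chemical rows parse with normalised xrefs", {
  f <- write_tmp(c(
    "#id\tname\tformula\tcharge\tmass\tinchi\tsmiles\txref",
    "MNXM3\tATP\tC10H12N5O13P3\t-4\t506.9957\tInChI=1S/x\tOP(=O)x\tchebi:15422",
    "MNXM9\tformate\t\t-1\t\t\t\t",
    "MNXM10\tmystery\tC2H6O\tn/a\t46.04\t\t\t"), "chem.tsv")
  expect_warning(parse_mnxref_chemicals(f), "non-integer charge")
  out <- suppressWarnings(parse_mnxref_chemicals(f))
  expect_length(out, 3L)
  atp <- out[[1]]
  expect_equal(atp$xrefs[["chebi"]], "CHEBI:15422")
  expect_equal(atp$xrefs[["mnx"]], "MNXM3")
  expect_equal(atp$charge, -4L)
  expect_equal(atp$monoisotopic_mass, 506.9957)
  expect_null(out[[2]]$formula)          # empty cell -> absent field
  expect_null(out[[3]]$charge)           # degenerate cell dropped
  dup <- write_tmp(c("A\tx\t\t\t\t\t\t", "A\ty\t\t\t\t\t\t"), "dup.tsv")
  expect_error(parse_mnxref_chemicals(dup), class = "kg_parse_error")
})

test_that("reaction equations follow the sign convention", {
  f <- write_tmp(c(
    "#id\tequation\tec\tbalance\txref",
    "RX1\t1 MNXM_glc + 1 MNXM_atp = 1 MNXM_g6p + 1 MNXM_adp\t2.7.1.2\ttrue\tkegg:R00299",
    "RX2\t2 A = 1 B\t\t\t",
    "RX3\t1 A = 1 A\t\tfalse\t"), "reac.tsv")
  expect_warning(parse_mnxref_reactions(f), "net-zero")
  out <- suppressWarnings(parse_mnxref_reactions(f))
  p1 <- out[[1]]$participants
  expect_equal(p1$stoichiometry, c(-1L, -1L, 1L, 1L))
  expect_equal(p1$chemical_id[p1$stoichiometry < 0],
               c("MNXM_glc", "MNXM_atp"))
  expect_equal(out[[1]]$xrefs[["kegg.reaction"]], "R00299")
  expect_true(isTRUE(out[[1]]$balance))
  expect_equal(out[[2]]$participants$stoichiometry, c(-2L, 1L))
  expect_true(is.na(out[[2]]$balance))
  expect_equal(nrow(out[[3]]$participants), 0L)
  bad <- write_tmp(c("R\t1 A extra = B"), "badeq.tsv")
  expect_error(suppressWarnings(parse_mnxref_reactions(bad)),
               class = "kg_parse_error")
})

test_that("ChEBI ontology tables parse into class nodes and relations", {
  comp <- write_tmp(c("CHEBI:1\tflavonoid", "CHEBI:2\tflavone",
                      "CHEBI:3\tapigenin", "CHEBI:4\tG6P",
                      "CHEBI:5\tglucose"), "cc.tsv")
  rel <- write_tmp(c("is_a\tCHEBI:3\tCHEBI:2",
                     "is_a\tCHEBI:2\tCHEBI:1",
                     "has_functional_parent\tCHEBI:4\tCHEBI:5",
                     "made_up_relation\tCHEBI:3\tCHEBI:1",
                     "is_a\tCHEBI:3\tCHEBI:99"), "cr.tsv")
  dat <- write_tmp(c("CHEBI:3\tFORMULA\tC15H10O5",
                     "CHEBI:3\tCHARGE\t0",
                     "CHEBI:3\tMONOISOTOPIC MASS\t270.052823",
                     "CHEBI:1\tFORMULA\t"), "cd.tsv")
  nm <- write_tmp("CHEBI:3\t4',5,7-trihydroxyflavone", "cn.tsv")
  warns <- character()
  out <- withCallingHandlers(
    parse_chebi_ontology(comp, rel, dat, nm),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("made_up_relation", warns)))
  expect_true(any(grepl("CHEBI:99", warns)))
  expect_length(out$chemicals, 5L)
  expect_length(out$relationships, 3L)
  api <- Filter(function(c) c$id == "CHEBI:3", out$chemicals)[[1]]
  expect_equal(api$formula, "C15H10O5")
  expect_equal(api$monoisotopic_mass, 270.052823)
  expect_true("4',5,7-trihydroxyflavone" %in% api$names)
  # class node without formula is still a valid node
  flav <- Filter(function(c) c$id == "CHEBI:1", out$chemicals)[[1]]
  expect_null(flav$formula)
  hfp <- Filter(function(r) r$type == "has_functional_parent",
                out$relationships)[[1]]
  expect_equal(hfp$from_id, "CHEBI:4")   # child -> parent direction
  expect_equal(hfp$to_id, "CHEBI:5")
})

test_that("protein table yields enzymes, expresses and deferred links", {
  f <- write_tmp(c(
    paste("uniprot", "entry", "name", "synonyms", "ec", "taxonomy_id",
          "reaction_xrefs", sep = "\t"),
    paste("P0A6V8", "GLK_ECOLI", "Glucokinase", "GLK", "2.7.1.2",
          "83333", "kegg.reaction:R00299", sep = "\t"),
    paste("P11111", "YYY_ECOLI", "Orphan", "", "1.1.1.1", "83333", "",
          sep = "\t"),
    paste("P0A6V8", "GLK_ECOLI", "Glucokinase II", "", "2.7.1.2",
          "562", "rhea:14797", sep = "\t")), "prot.tsv")
  out <- parse_protein_table(f)
  expect_length(out$enzymes, 2L)          # same uniprot collapses
  glk <- Filter(function(e) e$uniprot == "P0A6V8", out$enzymes)[[1]]
  expect_equal(glk$name, "Glucokinase")   # first-loaded name kept
  expect_true("Glucokinase II" %in% glk$names)
  expect_equal(nrow(out$expresses), 3L)   # two taxa for P0A6V8
  expect_equal(sum(out$expresses$uniprot == "P0A6V8"), 2L)
  expect_equal(nrow(out$reaction_links), 2L)
  expect_setequal(out$reaction_links$namespace,
                  c("kegg.reaction", "rhea"))
})

test_that("parsers tolerate comments, blank tails and CRLF", {
  f <- file.path(tempdir(), "crlf.tsv")
  con <- file(f, "wb")
  writeLines(c("# comment", "A\talanine\t\t\t\t\t\t", "", ""), con,
             sep = "\r\n")
  close(con)
  out <- parse_mnxref_chemicals(f)
  expect_length(out, 1L)
  expect_equal(out[[1]]$name, "alanine")
})
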