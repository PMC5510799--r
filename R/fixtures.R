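# Synthetic source data with known ground truth. The generator emulates
# the five source dialects (taxonomy dump, MNXref chemical/reaction
# tables, ChEBI ontology tables, protein table) at miniature scale:
# chemistry is organised in hydration "ladders" (each step adds H and O
# and lowers the charge by one) so that every generated reaction
# X(k) + H2O = X(k+1) + H+ is element- and charge-balanced by
# construction, and corrupting a reaction by stripping its proton is
# exactly recoverable by the balancer. Every ladder edge is used by at
# most one reaction, so frequent-pair detection never relabels backbone
# metabolites; only water and protons are cofactors (low-mass rule).

#' Specification for a synthetic fixture
#'
#' @param n_organisms Number of organisms (>= 1) including the root.
#' @param tree_depth Maximum depth of the taxonomy tree (>= 1).
#' @param n_enzymes Number of enzymes (>= 1).
#' @param n_reactions Number of reactions (>= 1).
#' @param n_chemicals Number of distinct chemicals (the first two are
#'   always protons and water so that balancing has its addable species).
#' @param fraction_unbalanced Fraction of reactions corrupted by removing
#'   their produced proton (in `[0, 1]`).
#' @param fraction_shared_xrefs Fraction of chemicals emitted in *both*
#'   the MNXref and ChEBI files under linked cross-references (in
#'   `[0, 1]`); these must merge to a single node at build time.
#' @param seed Integer RNG seed; the same seed yields byte-identical
#'   fixture files.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_organisms = 10L, tree_depth = 3L,
                         n_enzymes = 12L, n_reactions = 12L,
                         n_chemicals = 20L, fraction_unbalanced = 0.25,
                         fraction_shared_xrefs = 0.5, seed = 1L) {
  spec <- list(n_organisms = as.integer(n_organisms),
               tree_depth = as.integer(tree_depth),
               n_enzymes = as.integer(n_enzymes),
               n_reactions = as.integer(n_reactions),
               n_chemicals = as.integer(n_chemicals),
               fraction_unbalanced = fraction_unbalanced,
               fraction_shared_xrefs = fraction_shared_xrefs,
               seed = as.integer(seed))
  if (any(vapply(spec[1:5], function(x) is.na(x) || x < 1, logical(1))))
    kg_validation_error("all fixture counts must be >= 1")
  for (f in c("fraction_unbalanced", "fraction_shared_xrefs"))
    if (spec[[f]] < 0 || spec[[f]] > 1)
      kg_validation_error(sprintf("%s must be in [0, 1]", f))
  if (spec$n_chemicals < 3 && spec$fraction_unbalanced > 0)
    kg_validation_error(
      "n_chemicals must be >= 3 when fraction_unbalanced > 0")
  class(spec) <- "fixture_spec"
  spec
}

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  fn()
}

mnx_id <- function(i) sprintf("MNXM%d", i)
chebi_id <- function(i) sprintf("CHEBI:%d", 10000L + i)
kegg_rxn_id <- function(i) sprintf("R%05d", i)

#' Generate a synthetic source directory with known ground truth
#'
#' Writes all five source-file dialects into `out_dir` such that
#' [build_graph()] on the directory yields exactly the returned ground
#' truth. Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Ground-truth list: expected node and edge counts per type, the
#'   ids and pre-corruption participants of deliberately unbalanced
#'   reactions, the cross-source duplicate chemical pairs, and the
#'   canonical (post-merge) id of every chemical.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_chem <- spec$n_chemicals
  n_pool <- n_chem - 2L
  # Ladders of up to 4 chemicals over the pool (indices 3..n_chemicals).
  ladder_of <- integer(0)
  pos_in_ladder <- integer(0)
  if (n_pool > 0) {
    ladder_of <- (seq_len(n_pool) - 1L) %/% 4L
    pos_in_ladder <- (seq_len(n_pool) - 1L) %% 4L
  }
  # Ladder edges (consecutive pool indices within a ladder).
  edges <- which(diff(ladder_of) == 0L)  # edge j: pool j -> pool j+1
  if (spec$n_reactions > length(edges))
    kg_validation_error(sprintf(
      "n_chemicals=%d supports at most %d reactions (need n_reactions=%d)",
      n_chem, length(edges), spec$n_reactions))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  with_seed(spec$seed, function() {
    ## ---- organisms ------------------------------------------------
    n_org <- spec$n_organisms
    tax_ids <- c("1", if (n_org > 1) as.character(100L + seq_len(n_org - 1L)))
    depth <- c(0L, rep(NA_integer_, n_org - 1L))
    parent <- c("1", rep(NA_character_, n_org - 1L))
    for (i in seq_len(n_org - 1L)) {
      if (i < spec$tree_depth) {
        parent[i + 1L] <- tax_ids[i]          # guarantee the target depth
        depth[i + 1L] <- depth[i] + 1L
      } else {
        cand <- which(depth < spec$tree_depth & !is.na(depth))
        pick <- cand[sample.int(length(cand), 1L)]
        parent[i + 1L] <- tax_ids[pick]
        depth[i + 1L] <- depth[pick] + 1L
      }
    }
    nodes_lines <- sprintf("%s\t|\t%s\t|\t%s\t|", tax_ids, parent,
                           ifelse(tax_ids == "1", "no rank", "species"))
    names_lines <- c(
      sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|", tax_ids,
              ifelse(tax_ids == "1", "root",
                     paste("Synthorg", tax_ids))),
      sprintf("%s\t|\t%s\t|\t\t|\tsynonym\t|",
              tax_ids[c(FALSE, TRUE)],
              paste("Synthorg strain", tax_ids[c(FALSE, TRUE)])))
    write_lf(nodes_lines, file.path(out_dir, "nodes.dmp"))
    write_lf(names_lines, file.path(out_dir, "names.dmp"))

    ## ---- chemicals ------------------------------------------------
    # index 1 = proton, 2 = water, 3.. = ladder pool.
    formulas <- character(n_chem)
    charges <- integer(n_chem)
    names_chem <- character(n_chem)
    formulas[1] <- "H";   charges[1] <- 1L;  names_chem[1] <- "H(+)"
    formulas[2] <- "H2O"; charges[2] <- 0L;  names_chem[2] <- "water"
    if (n_pool > 0) {
      n_ladders <- max(ladder_of) + 1L
      base_c <- sample(5:10, n_ladders, replace = TRUE)
      base_h <- sample(8:16, n_ladders, replace = TRUE)
      base_o <- sample(2:6, n_ladders, replace = TRUE)
      base_n <- sample(0:2, n_ladders, replace = TRUE)
      for (j in seq_len(n_pool)) {
        lad <- ladder_of[j] + 1L
        p <- pos_in_ladder[j]
        nn <- base_n[lad]
        formulas[j + 2L] <- paste0(
          "C", base_c[lad], "H", base_h[lad] + p, if (nn > 0)
            paste0("N", nn), "O", base_o[lad] + p)
        charges[j + 2L] <- -p
        names_chem[j + 2L] <- sprintf("metabolite %d-%d", lad, p)
      }
    }
    masses <- vapply(formulas, function(f) monoisotopic_mass(f),
                     numeric(1))
    shared_n <- round(spec$fraction_shared_xrefs * n_chem)
    shared <- seq_len(shared_n)   # first shared_n chemicals in both files

    chem_lines <- vapply(seq_len(n_chem), function(i) {
      xref <- if (i %in% shared) sprintf("chebi:%s", chebi_id(i)) else ""
      paste(mnx_id(i), names_chem[i], formulas[i], charges[i],
            sprintf("%.6f", masses[i]), "", "", xref, sep = "\t")
    }, character(1))
    write_lf(c("#id\tname\tformula\tcharge\tmass\tinchi\tsmiles\txref",
               chem_lines), file.path(out_dir, "chem_prop.tsv"))

    comp_lines <- vapply(shared, function(i)
      paste(chebi_id(i), names_chem[i], sep = "\t"), character(1))
    data_lines <- unlist(lapply(shared, function(i) c(
      paste(chebi_id(i), "FORMULA", formulas[i], sep = "\t"),
      paste(chebi_id(i), "CHARGE", charges[i], sep = "\t"),
      paste(chebi_id(i), "MONOISOTOPIC MASS", sprintf("%.6f", masses[i]),
            sep = "\t"))))
    cn_lines <- vapply(shared, function(i)
      paste(chebi_id(i), paste0(names_chem[i], " (synthetic)"),
            sep = "\t"), character(1))
    # Ontology edges: each ladder step with both ends in the ChEBI subset
    # records the product as functional child of the substrate.
    rel_lines <- character()
    n_chem_rels <- 0L
    for (e in edges) {
      lo <- e + 2L; hi <- e + 3L     # chemical indices
      if (lo %in% shared && hi %in% shared) {
        rel_lines <- c(rel_lines,
                       paste("has_functional_parent", chebi_id(hi),
                             chebi_id(lo), sep = "\t"))
        n_chem_rels <- n_chem_rels + 1L
      }
    }
    write_lf(c("#chebi_id\tname", comp_lines),
             file.path(out_dir, "chebi_compounds.tsv"))
    write_lf(c("#type\tchild\tparent", rel_lines),
             file.path(out_dir, "chebi_relations.tsv"))
    write_lf(c("#chebi_id\tkey\tvalue", data_lines),
             file.path(out_dir, "chebi_data.tsv"))
    write_lf(c("#chebi_id\tsynonym", cn_lines),
             file.path(out_dir, "chebi_names.tsv"))

    ## ---- reactions ------------------------------------------------
    use_edges <- sort(sample(edges, spec$n_reactions))
    n_unbal <- round(spec$fraction_unbalanced * spec$n_reactions)
    unbal <- sort(sample(seq_len(spec$n_reactions), n_unbal))
    canon <- function(i) if (i %in% shared) chebi_id(i) else mnx_id(i)
    rxn_ids <- sprintf("MNXR%d", seq_len(spec$n_reactions))
    original <- list()
    reac_lines <- vapply(seq_len(spec$n_reactions), function(r) {
      e <- use_edges[r]
      lo <- e + 2L; hi <- e + 3L
      eq <- sprintf("1 %s + 1 %s = 1 %s + 1 %s",
                    mnx_id(lo), mnx_id(2L), mnx_id(hi), mnx_id(1L))
      corrupt <- r %in% unbal
      if (corrupt)
        eq <- sprintf("1 %s + 1 %s = 1 %s", mnx_id(lo), mnx_id(2L),
                      mnx_id(hi))
      original[[rxn_ids[r]]] <<- data.frame(
        chemical_id = c(canon(lo), canon(2L), canon(hi), canon(1L)),
        stoichiometry = c(-1L, -1L, 1L, 1L),
        stringsAsFactors = FALSE)
      paste(rxn_ids[r], eq, sprintf("2.7.1.%d", r),
            if (corrupt) "false" else "true",
            sprintf("kegg:%s", kegg_rxn_id(r)), sep = "\t")
    }, character(1))
    write_lf(c("#id\tequation\tec\tbalance\txref", reac_lines),
             file.path(out_dir, "reac_prop.tsv"))

    ## ---- proteins -------------------------------------------------
    org_cycle <- rep(tax_ids, length.out = spec$n_enzymes)
    rxn_cycle <- rep(seq_len(spec$n_reactions),
                     length.out = spec$n_enzymes)
    prot_lines <- vapply(seq_len(spec$n_enzymes), function(k) {
      paste(sprintf("P%05d", 10000L + k),
            sprintf("ENZ%03d_SYNTH", k),
            sprintf("synthetic kinase %d", k),
            sprintf("kinase %d;EC-2.7 enzyme %d", k, k),
            sprintf("2.7.1.%d", rxn_cycle[k]),
            org_cycle[k],
            sprintf("kegg.reaction:%s", kegg_rxn_id(rxn_cycle[k])),
            sep = "\t")
    }, character(1))
    write_lf(c(paste("uniprot", "entry", "name", "synonyms", "ec",
                     "taxonomy_id", "reaction_xrefs", sep = "\t"),
               prot_lines), file.path(out_dir, "proteins.tsv"))

    ## ---- ground truth --------------------------------------------
    list(
      nodes = c(Organism = n_org, Enzyme = spec$n_enzymes,
                Reaction = spec$n_reactions, Chemical = n_chem),
      edges = c(is_a_organism = n_org - 1L,
                expresses = spec$n_enzymes,
                catalysed_by = spec$n_enzymes,
                reaction_chemical = 4L * spec$n_reactions,
                has_cofactor = 2L * spec$n_reactions,
                has_reactant = 2L * spec$n_reactions,
                chemical_chemical = n_chem_rels),
      unbalanced_ids = rxn_ids[unbal],
      original_participants = original[rxn_ids[unbal]],
      shared_pairs = data.frame(
        mnx = vapply(shared, mnx_id, character(1)),
        chebi = vapply(shared, chebi_id, character(1)),
        stringsAsFactors = FALSE),
      canonical_chemical_ids = vapply(seq_len(n_chem), canon,
                                      character(1)),
      spec = spec)
  })
}

#' Random reaction network for pathway-search verification
#'
#' Builds a small in-memory graph with random `has_reactant` wiring and
#' random stoichiometry signs (no chemistry attached: pathway search only
#' reads signs), plus one host organism whose single enzyme catalyses a
#' random subset of reactions. Used to compare [find_pathways()] against
#' brute-force enumeration.
#'
#' @param n_chemicals,n_reactions Network size.
#' @param seed RNG seed.
#' @param host_fraction Fraction of reactions catalysed by the host's
#'   enzyme.
#' @return List with `graph` (a `kgraph`), `host` (taxon id) and
#'   `target` (a chemical id chosen away from the host set when
#'   possible).
#' @export
random_reaction_graph <- function(n_chemicals = 25L, n_reactions = 25L,
                                  seed = 1L, host_fraction = 0.3) {
  with_seed(seed, function() {
      g <- kgraph()
      chems <- sprintf("C%03d", seq_len(n_chemicals))
      for (id in chems)
        upsert_node(g, "Chemical", chemical_entity(id = id, name = id))
      upsert_node(g, "Organism", organism_entity("9000", name = "host"))
      upsert_node(g, "Enzyme", enzyme_entity("P99999", name = "host enzyme"))
      add_relationship(g, relationship(
        "Organism", "9000", "expresses", "Enzyme", "P99999",
        properties = list(source = "uniprot")))
      n_host <- max(1L, round(host_fraction * n_reactions))
      host_rxns <- sample.int(n_reactions, n_host)
      for (r in seq_len(n_reactions)) {
        rid <- sprintf("R%03d", r)
        k <- sample(2:4, 1L)
        members <- sample(chems, k)
        signs <- c(-1L, 1L, sample(c(-1L, 1L), k - 2L, replace = TRUE))
        mags <- sample(1:2, k, replace = TRUE)
        p <- data.frame(chemical_id = members,
                        stoichiometry = signs * mags,
                        role = "reactant", stringsAsFactors = FALSE)
        upsert_node(g, "Reaction", reaction_entity(id = rid,
                                                   participants = p))
        for (i in seq_len(k))
          add_relationship(g, relationship(
            "Reaction", rid, "has_reactant", "Chemical", members[i],
            properties = list(stoichiometry = p$stoichiometry[i])))
        if (r %in% host_rxns)
          add_relationship(g, relationship(
            "Reaction", rid, "catalysed_by", "Enzyme", "P99999",
            properties = list(source = "kegg")))
      }
      hr <- graph_relationships(g, "has_reactant")
      cb <- graph_relationships(g, "catalysed_by")
      native <- unique(hr$to_id[hr$from_id %in% cb$from_id])
      non_native <- setdiff(chems, native)
      target <- if (length(non_native) > 0)
        non_native[sample.int(length(non_native), 1L)]
      else chems[sample.int(length(chems), 1L)]
      list(graph = g, host = "9000", target = target)
  })
}

#' Synthetic flavonoid-like chemical ontology
#'
#' A stand-in, generated in code, for a flavonoid class hierarchy: one
#' root class node, a layer of generic subclass nodes without formulas,
#' and `n_with_formula` concrete species with molecular formulas hanging
#' below them through mixed ontology relation types. The generic class
#' layer exercises the formula filter of [descendant_chemicals()]; an
#' unrelated decoy branch verifies that only true descendants are
#' returned.
#'
#' @param n_with_formula Number of concrete (formula-bearing) descendant
#'   species.
#' @param n_classes Number of formula-less intermediate class nodes.
#' @param seed RNG seed.
#' @return A `kgraph`.
#' @export
synthetic_flavonoid_ontology <- function(n_with_formula = 1081L,
                                         n_classes = 30L, seed = 1L) {
  with_seed(seed, function() {
      g <- kgraph()
      root <- "CHEBI:47916"
      upsert_node(g, "Chemical", chemical_entity(
        id = root, name = "flavonoid", xrefs = c(chebi = root)))
      classes <- sprintf("CHEBI:9%04d", seq_len(n_classes))
      for (i in seq_along(classes)) {
        upsert_node(g, "Chemical", chemical_entity(
          id = classes[i], name = sprintf("flavonoid class %d", i),
          xrefs = c(chebi = classes[i])))
        parent <- if (i <= 3) root else
          classes[sample.int(i - 1L, 1L)]
        add_relationship(g, relationship(
          "Chemical", classes[i], "is_a", "Chemical", parent))
      }
      rel_types <- c("is_a", "has_functional_parent",
                     "is_conjugate_base_of", "has_parent_hydride")
      for (k in seq_len(n_with_formula)) {
        id <- sprintf("CHEBI:1%05d", k)
        formula <- sprintf("C15H%dO%d", 10 + (k %% 7), 4 + (k %% 5))
        upsert_node(g, "Chemical", chemical_entity(
          id = id, name = sprintf("synthetic flavonoid %d", k),
          formula = formula,
          inchi = sprintf("InChI=1S/%s/synth%d", formula, k),
          xrefs = c(chebi = id)))
        parent <- classes[1L + (k %% n_classes)]
        add_relationship(g, relationship(
          "Chemical", id, rel_types[1L + (k %% length(rel_types))],
          "Chemical", parent))
      }
      # Decoy branch outside the flavonoid subtree.
      upsert_node(g, "Chemical", chemical_entity(
        id = "CHEBI:35366", name = "fatty acid"))
      for (k in seq_len(25L)) {
        id <- sprintf("CHEBI:8%04d", k)
        upsert_node(g, "Chemical", chemical_entity(
          id = id, name = sprintf("synthetic fatty acid %d", k),
          formula = sprintf("C%dH%dO2", 10 + k, 20 + 2 * k)))
        add_relationship(g, relationship(
          "Chemical", id, "is_a", "Chemical", "CHEBI:35366"))
      }
      g
  })
}

#' Synthetic taxon metabolome graph
#'
#' A stand-in, generated in code, for a species-level metabolome wired
#' through the Organism-Enzyme-Reaction-Chemical pattern: strain
#' organisms sit one `is_a` hop below the parent taxon, each strain
#' expresses enzymes catalysing reactions whose products are the
#' metabolites. `n_in_range` metabolites have monoisotopic masses
#' strictly inside (400, 500) Da; decoys outside the window, boundary
#' masses at exactly 400 and 500, and in-window chemicals attached only
#' as cofactors verify the filters of [taxon_metabolome()].
#'
#' @param n_in_range Number of metabolites inside the (400, 500) window.
#' @param n_below,n_above Numbers of out-of-window decoy metabolites.
#' @param n_cofactor_decoys In-window chemicals attached via
#'   `has_cofactor` only (must not be returned).
#' @param taxon Parent taxon id (default `"562"`).
#' @param seed RNG seed.
#' @return A `kgraph`.
#' @export
synthetic_strain_metabolome <- function(n_in_range = 111L, n_below = 20L,
                                        n_above = 20L,
                                        n_cofactor_decoys = 5L,
                                        taxon = "562", seed = 1L) {
  with_seed(seed, function() {
      g <- kgraph()
      upsert_node(g, "Organism", organism_entity(
        taxon, name = "Escherichia coli"))
      strains <- c("83333", "83334", "199310")
      for (s in strains) {
        upsert_node(g, "Organism", organism_entity(
          s, name = sprintf("strain %s", s), parent_taxonomy = taxon))
        add_relationship(g, relationship(
          "Organism", s, "is_a", "Organism", taxon))
      }
      masses <- c(400 + 100 * seq_len(n_in_range) / (n_in_range + 1),
                  300 + seq_len(n_below),
                  500 + 2 * seq_len(n_above),
                  400, 500)
      n_total <- length(masses)
      upsert_node(g, "Chemical", chemical_entity(
        id = "SUBSTRATE", name = "shared substrate",
        monoisotopic_mass = 180.06))
      for (i in seq_len(n_total)) {
        cid <- sprintf("MET%04d", i)
        upsert_node(g, "Chemical", chemical_entity(
          id = cid, name = sprintf("synthetic metabolite %d", i),
          monoisotopic_mass = masses[i], charge = 0L))
        rid <- sprintf("RMET%04d", i)
        p <- data.frame(chemical_id = c("SUBSTRATE", cid),
                        stoichiometry = c(-1L, 1L), role = "reactant",
                        stringsAsFactors = FALSE)
        upsert_node(g, "Reaction", reaction_entity(id = rid,
                                                   participants = p))
        add_relationship(g, relationship(
          "Reaction", rid, "has_reactant", "Chemical", "SUBSTRATE",
          properties = list(stoichiometry = -1L)))
        add_relationship(g, relationship(
          "Reaction", rid, "has_reactant", "Chemical", cid,
          properties = list(stoichiometry = 1L)))
        eid <- sprintf("P%05d", 50000L + i)
        upsert_node(g, "Enzyme", enzyme_entity(
          eid, name = sprintf("synthetic enzyme %d", i)))
        strain <- strains[1L + (i %% length(strains))]
        add_relationship(g, relationship(
          "Organism", strain, "expresses", "Enzyme", eid,
          properties = list(source = "uniprot")))
        add_relationship(g, relationship(
          "Reaction", rid, "catalysed_by", "Enzyme", eid,
          properties = list(source = "kegg")))
      }
      # In-window chemicals reachable only through has_cofactor edges.
      for (j in seq_len(n_cofactor_decoys)) {
        cid <- sprintf("COF%03d", j)
        upsert_node(g, "Chemical", chemical_entity(
          id = cid, name = sprintf("cofactor decoy %d", j),
          monoisotopic_mass = 450 + j / 10))
        rid <- sprintf("RMET%04d", j)
        add_relationship(g, relationship(
          "Reaction", rid, "has_cofactor", "Chemical", cid,
          properties = list(stoichiometry = -1L)))
      }
      g
  })
}

#' Worked-example graph: hexokinase-type reactions in E. coli K-12
#'
#' A curated miniature graph around the ATP:D-glucose
#' 6-phosphotransferase reaction (KEGG R00299): Escherichia coli K-12
#' (taxon 83333, is_a child of taxon 562) expresses Glucokinase, which
#' catalyses R00299 converting D-glucopyranose to
#' D-glucopyranose 6-phosphate with the ATP/ADP couple. Two further
#' ATP-consuming kinase reactions are included so that ATP/ADP satisfy
#' the frequent-pair rule and cofactor annotation is computed, not
#' hard-coded. With `protons = TRUE` each reaction carries its produced
#' proton and is exactly element- and charge-balanced.
#'
#' @param protons Include the produced proton in each reaction.
#' @return A `kgraph` with cofactors annotated.
#' @export
hexokinase_demo_graph <- function(protons = FALSE) {
  g <- kgraph()
  upsert_node(g, "Organism", organism_entity(
    "562", name = "Escherichia coli",
    names = c("Bacillus coli Migula 1895")))
  upsert_node(g, "Organism", organism_entity(
    "83333", name = "Escherichia coli K-12", parent_taxonomy = "562"))
  add_relationship(g, relationship(
    "Organism", "83333", "is_a", "Organism", "562"))

  chem <- function(id, name, formula, charge, kegg = NULL) {
    xr <- c(chebi = id)
    if (!is.null(kegg)) xr["kegg.compound"] <- kegg
    upsert_node(g, "Chemical", chemical_entity(
      id = id, name = name, formula = formula, charge = charge,
      monoisotopic_mass = monoisotopic_mass(formula), xrefs = xr))
  }
  chem("CHEBI:4167", "D-glucopyranose", "C6H12O6", 0L, "C00031")
  chem("CHEBI:61548", "D-glucopyranose 6-phosphate", "C6H11O9P", -2L,
       "C00092")
  chem("CHEBI:30616", "ATP(4-)", "C10H12N5O13P3", -4L, "C00002")
  chem("CHEBI:456216", "ADP(3-)", "C10H12N5O10P2", -3L, "C00008")
  chem("CHEBI:17754", "glycerol", "C3H8O3", 0L, "C00116")
  chem("CHEBI:57597", "sn-glycerol 3-phosphate(2-)", "C3H7O6P", -2L,
       "C00093")
  chem("CHEBI:37721", "D-fructose", "C6H12O6", 0L, "C00095")
  chem("CHEBI:61527", "D-fructose 6-phosphate(2-)", "C6H11O9P", -2L,
       "C00085")
  if (protons) chem("CHEBI:15378", "H(+)", "H", 1L, "C00080")

  add_relationship(g, relationship(
    "Chemical", "CHEBI:61548", "has_functional_parent", "Chemical",
    "CHEBI:4167"))

  kinase <- function(rid, kegg, name, substrate, product) {
    ids <- c(substrate, "CHEBI:30616", product, "CHEBI:456216",
             if (protons) "CHEBI:15378")
    st <- c(-1L, -1L, 1L, 1L, if (protons) 1L)
    p <- data.frame(chemical_id = ids, stoichiometry = st,
                    role = "reactant", stringsAsFactors = FALSE)
    upsert_node(g, "Reaction", reaction_entity(
      id = rid, name = name, ec = "2.7.1.2",
      xrefs = c(kegg.reaction = kegg, mnx = paste0("MNX", rid)),
      source = "mnxref", participants = p))
    for (i in seq_len(nrow(p)))
      add_relationship(g, relationship(
        "Reaction", rid, "has_reactant", "Chemical", ids[i],
        properties = list(stoichiometry = st[i])))
  }
  kinase("MNXR_R00299", "R00299", "ATP:D-glucose 6-phosphotransferase",
         "CHEBI:4167", "CHEBI:61548")
  kinase("MNXR_R00847", "R00847", "ATP:glycerol 3-phosphotransferase",
         "CHEBI:17754", "CHEBI:57597")
  kinase("MNXR_R00760", "R00760", "ATP:D-fructose 6-phosphotransferase",
         "CHEBI:37721", "CHEBI:61527")

  enz <- function(uniprot, entry, name, rid) {
    upsert_node(g, "Enzyme", enzyme_entity(
      uniprot, entry = entry, ec_code = "2.7.1.2", name = name))
    add_relationship(g, relationship(
      "Organism", "83333", "expresses", "Enzyme", uniprot,
      properties = list(source = "uniprot")))
    add_relationship(g, relationship(
      "Reaction", rid, "catalysed_by", "Enzyme", uniprot,
      properties = list(source = "kegg")))
  }
  enz("P0A6V8", "GLK_ECOLI", "Glucokinase", "MNXR_R00299")
  enz("P0A6F3", "GLPK_ECOLI", "Glycerol kinase", "MNXR_R00847")
  enz("P0AEW9", "FRK_ECOLI", "Fructokinase", "MNXR_R00760")

  annotate_cofactors(g, min_pair_count = 2L)
  g
}
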