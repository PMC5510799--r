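# Graph build orchestration: parse -> normalise -> merge -> rewire ->
# cofactor annotation -> balancing. The source directory holds the five
# flat-file dialects (taxonomy dump pair, MNXref chemical and reaction
# tables, ChEBI ontology tables, protein table); any missing file is
# tolerated with a warning so partial graphs can be built.

SOURCE_FILES <- list(
  tax_nodes = "nodes.dmp", tax_names = "names.dmp",
  chem_prop = "chem_prop.tsv", reac_prop = "reac_prop.tsv",
  chebi_compounds = "chebi_compounds.tsv",
  chebi_relations = "chebi_relations.tsv",
  chebi_data = "chebi_data.tsv", chebi_names = "chebi_names.tsv",
  proteins = "proteins.tsv")

#' Default build configuration
#'
#' @param ... Named overrides, merged over the defaults:
#'   `namespace_map` (extra token mappings per context),
#'   `source_precedence` (`chemical`, `reaction` character vectors),
#'   `cofactor$min_pair_count` (`NULL` = `max(2, 5%)` of reactions),
#'   `balance$addable_species`, `balance$max_coefficient`,
#'   `pathway$max_len`.
#' @return Nested configuration list.
#' @export
kg_config <- function(...) {
  cfg <- list(
    namespace_map = list(Chemical = character(), Reaction = character()),
    source_precedence = list(chemical = c("chebi", "mnxref"),
                             reaction = c("mnxref", "kegg")),
    cofactor = list(min_pair_count = NULL),
    balance = list(addable_species = default_addable_species(),
                   max_coefficient = 20L, search_budget = 200000L),
    pathway = list(max_len = 8L))
  modifyList(cfg, list(...))
}

#' Read a YAML configuration file
#'
#' Keys mirror [kg_config()]; flags given on the command line override
#' config values, which override the defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_kg_config <- function(path) {
  if (!file.exists(path)) kg_io_error(sprintf("config not found: %s", path))
  do.call(kg_config, yaml::read_yaml(path) %||% list())
}

#' Build a knowledge graph from a source directory
#'
#' Orchestrates the full population pipeline: parse the flat files,
#' normalise cross-reference namespaces, merge chemicals that share
#' accessions across sources (transitively), repoint reaction participants
#' and ontology edges to the canonical chemical keys, resolve deferred
#' enzyme-reaction links through reaction cross-references, annotate
#' cofactors, and run the balancing pass (which writes the `balance` flag
#' and corrected stoichiometries). Any link still unresolved at the end is
#' listed in the build log and dropped.
#'
#' @param source_dir Directory containing the source files (see the
#'   package vignette for the dialects).
#' @param config Configuration list from [kg_config()] /
#'   [read_kg_config()].
#' @return List with `graph` (a `kgraph`), `report` (chemical
#'   `kg_merge_report`) and `log` (character vector of build messages).
#' @export
build_graph <- function(source_dir, config = kg_config()) {
  if (!dir.exists(source_dir))
    kg_io_error(sprintf("source directory not found: %s", source_dir))
  path <- function(nm) file.path(source_dir, SOURCE_FILES[[nm]])
  have <- function(nm) file.exists(path(nm))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  graph <- kgraph()

  # --- organisms -----------------------------------------------------
  tax_rels <- list()
  if (have("tax_nodes") && have("tax_names")) {
    tax <- parse_taxonomy_dump(path("tax_nodes"), path("tax_names"))
    for (o in tax$organisms) upsert_node(graph, "Organism", o)
    tax_rels <- tax$relationships
    note("organisms: %d parsed", length(tax$organisms))
  } else {
    warning("taxonomy dump missing; no organisms loaded", call. = FALSE)
    note("organisms: source files missing")
  }

  # --- chemicals (MNXref + ChEBI), merged ----------------------------
  mnx_chems <- if (have("chem_prop"))
    parse_mnxref_chemicals(path("chem_prop")) else list()
  chebi <- if (have("chebi_compounds") && have("chebi_relations") &&
               have("chebi_data") && have("chebi_names"))
    parse_chebi_ontology(path("chebi_compounds"), path("chebi_relations"),
                         path("chebi_data"), path("chebi_names"))
  else list(chemicals = list(), relationships = list())
  if (length(mnx_chems) == 0 && length(chebi$chemicals) == 0)
    note("chemicals: no source files found")

  merged <- merge_entities(c(chebi$chemicals, mnx_chems),
                           precedence = config$source_precedence$chemical,
                           label = "Chemical")
  for (chem in merged$entities) upsert_node(graph, "Chemical", chem)
  note("chemicals: %d after merging %d source records",
       length(merged$entities),
       length(mnx_chems) + length(chebi$chemicals))
  remap1 <- function(id) {
    m <- merged$report$merge_map
    if (id %in% names(m)) unname(m[[id]]) else id
  }

  # --- reactions -----------------------------------------------------
  reactions <- if (have("reac_prop"))
    parse_mnxref_reactions(path("reac_prop")) else list()
  rxn_xref_index <- new.env(hash = TRUE, parent = emptyenv())
  dropped_participants <- 0L
  for (rxn in reactions) {
    p <- rxn$participants
    if (nrow(p) > 0) {
      p$chemical_id <- vapply(p$chemical_id, remap1, character(1))
      known <- p$chemical_id %in% graph_nodes(graph, "Chemical")
      if (any(!known)) {
        dropped_participants <- dropped_participants + sum(!known)
        p <- p[known, , drop = FALSE]
      }
      rxn$participants <- p
    }
    upsert_node(graph, "Reaction", rxn)
    for (ns in names(rxn$xrefs))
      rxn_xref_index[[paste(ns, rxn$xrefs[[ns]], sep = "\r")]] <- rxn$id
  }
  note("reactions: %d parsed", length(reactions))
  if (dropped_participants > 0)
    note("reactions: %d participant(s) referenced unknown chemicals, dropped",
         dropped_participants)

  # --- enzymes -------------------------------------------------------
  prot <- if (have("proteins")) parse_protein_table(path("proteins"))
  else list(enzymes = list(),
            expresses = data.frame(taxonomy = character(),
                                   uniprot = character(),
                                   source = character()),
            reaction_links = data.frame(uniprot = character(),
                                        namespace = character(),
                                        accession = character()))
  for (e in prot$enzymes) upsert_node(graph, "Enzyme", e)
  note("enzymes: %d parsed", length(prot$enzymes))

  # --- relationships -------------------------------------------------
  dropped_rels <- 0L
  add_or_drop <- function(rel) {
    ok <- tryCatch({ add_relationship(graph, rel); TRUE },
                   kg_error = function(e) FALSE)
    if (!ok) dropped_rels <<- dropped_rels + 1L
    ok
  }
  for (r in tax_rels) add_or_drop(r)
  for (r in chebi$relationships) {
    r$from_id <- remap1(r$from_id)
    r$to_id <- remap1(r$to_id)
    add_or_drop(r)
  }
  for (rid in graph_nodes(graph, "Reaction")) {
    rxn <- get_node(graph, "Reaction", rid)
    p <- rxn$participants
    for (i in seq_len(nrow(p)))
      add_or_drop(relationship(
        "Reaction", rid, "has_reactant", "Chemical", p$chemical_id[i],
        properties = list(stoichiometry = p$stoichiometry[i])))
  }
  ex <- prot$expresses
  deferred_taxa <- character()
  for (i in seq_len(nrow(ex))) {
    if (is.null(get_node(graph, "Organism", ex$taxonomy[i]))) {
      deferred_taxa <- c(deferred_taxa, ex$taxonomy[i])
      next
    }
    add_or_drop(relationship("Organism", ex$taxonomy[i], "expresses",
                             "Enzyme", ex$uniprot[i],
                             properties = list(source = ex$source[i])))
  }
  if (length(deferred_taxa) > 0) {
    warning(sprintf("unknown taxonomy id(s) in protein table: %s",
                    paste(unique(deferred_taxa), collapse = ", ")),
            call. = FALSE)
    note("expresses: %d link(s) dropped (unknown taxa: %s)",
         length(deferred_taxa),
         paste(unique(deferred_taxa), collapse = ", "))
  }
  rl <- prot$reaction_links
  unresolved <- 0L
  for (i in seq_len(nrow(rl))) {
    rid <- rxn_xref_index[[paste(rl$namespace[i], rl$accession[i],
                                 sep = "\r")]]
    if (is.null(rid)) { unresolved <- unresolved + 1L; next }
    add_or_drop(relationship("Reaction", rid, "catalysed_by", "Enzyme",
                             rl$uniprot[i],
                             properties = list(source = rl$namespace[i])))
  }
  if (unresolved > 0)
    note("catalysed_by: %d reaction xref(s) unresolved, links dropped",
         unresolved)
  if (dropped_rels > 0)
    note("relationships: %d dropped (dangling or invalid)", dropped_rels)

  # --- annotation and balancing -------------------------------------
  mpc <- config$cofactor$min_pair_count %||%
    default_min_pair_count(node_count(graph, "Reaction"))
  n_cof <- annotate_cofactors(graph, mpc)
  note("cofactors: %d edge(s) relabelled (min_pair_count=%d)", n_cof, mpc)
  bal <- balance_graph(graph, config)
  if (nrow(bal) > 0)
    note("balance: %s",
         paste(sprintf("%s=%d", names(table(bal$status)),
                       as.integer(table(bal$status))), collapse = ", "))

  if (node_count(graph) == 0)
    warning("empty source directory: built an empty graph", call. = FALSE)

  list(graph = graph, report = merged$report, log = log)
}
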