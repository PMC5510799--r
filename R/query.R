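# Cross-domain query operations over the knowledge graph: reaction
# context in an organism, chemical-ontology descendants, taxon-restricted
# metabolome windows, stoichiometry-directed pathway search and pathway
# enzyme lookup. Each operation has a brute-force-verifiable contract on
# small graphs.

#' Subgraph context of a reaction within an organism
#'
#' Answers "does this reaction occur in this organism?". The result is the
#' subgraph of: the reaction; its chemicals (both `has_reactant` and
#' `has_cofactor` edges); the enzymes linked by `catalysed_by` that are
#' expressed by the organism with the given taxonomy id; that organism and
#' its `is_a` parent; and any chemical-chemical edges among the returned
#' chemicals. An empty subgraph means the reaction does not occur in that
#' organism (or reaction/taxon are unknown).
#'
#' @param graph A `kgraph`.
#' @param reaction_xref Length-2 character vector `(namespace, accession)`
#'   identifying the reaction, e.g. `c("kegg.reaction", "R00299")`.
#' @param taxon_id Organism taxonomy id, e.g. `"83333"`.
#' @return A `kg_subgraph`: list with `nodes` (data frame `label`, `key`)
#'   and `relationships` (list of [relationship()] records).
#' @export
reaction_context <- function(graph, reaction_xref, taxon_id) {
  empty <- empty_subgraph()
  ns <- reaction_xref[[1]]; acc <- reaction_xref[[2]]
  rid <- NULL
  for (id in graph_nodes(graph, "Reaction")) {
    rxn <- get_node(graph, "Reaction", id)
    if (!is.null(rxn$xrefs[ns]) && !is.na(rxn$xrefs[ns]) &&
        rxn$xrefs[[ns]] == acc) { rid <- id; break }
  }
  if (is.null(rid) || is.null(get_node(graph, "Organism", taxon_id)))
    return(empty)

  rels <- graph_relationships(graph)
  cat_by <- rels[rels$type == "catalysed_by" & rels$from_id == rid, ,
                 drop = FALSE]
  expr <- rels[rels$type == "expresses" & rels$from_id == taxon_id, ,
               drop = FALSE]
  enzymes <- intersect(cat_by$to_id, expr$to_id)
  if (length(enzymes) == 0) return(empty)

  keep_rels <- list()
  nodes <- list()
  add_node <- function(label, key)
    nodes[[length(nodes) + 1L]] <<- data.frame(label = label, key = key,
                                               stringsAsFactors = FALSE)
  add_node("Reaction", rid)
  chem_edges <- rels[rels$from_id == rid &
                       rels$type %in% c("has_reactant", "has_cofactor"), ,
                     drop = FALSE]
  for (i in seq_len(nrow(chem_edges))) add_node("Chemical",
                                                chem_edges$to_id[i])
  for (e in enzymes) add_node("Enzyme", e)
  add_node("Organism", taxon_id)
  parent_edge <- rels[rels$type == "is_a" & rels$from_label == "Organism" &
                        rels$from_id == taxon_id, , drop = FALSE]
  for (i in seq_len(nrow(parent_edge))) add_node("Organism",
                                                 parent_edge$to_id[i])
  chems <- unique(chem_edges$to_id)
  chem_chem <- rels[rels$type %in% CHEMICAL_RELATION_TYPES &
                      rels$from_label == "Chemical" &
                      rels$from_id %in% chems & rels$to_id %in% chems, ,
                    drop = FALSE]

  keep <- rbind(
    chem_edges,
    cat_by[cat_by$to_id %in% enzymes, , drop = FALSE],
    expr[expr$to_id %in% enzymes, , drop = FALSE],
    parent_edge,
    chem_chem)
  nodes_df <- unique(do.call(rbind, nodes))
  structure(list(nodes = nodes_df, relationships = df_to_rels(keep)),
            class = "kg_subgraph")
}

empty_subgraph <- function() {
  structure(list(nodes = data.frame(label = character(), key = character(),
                                    stringsAsFactors = FALSE),
                 relationships = list()),
            class = "kg_subgraph")
}

df_to_rels <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    props <- list()
    if (!is.na(df$stoichiometry[i]))
      props$stoichiometry <- as.integer(df$stoichiometry[i])
    if (!is.na(df$source[i])) props$source <- df$source[i]
    relationship(df$from_label[i], df$from_id[i], df$type[i],
                 df$to_label[i], df$to_id[i], props)
  })
}

#' @export
print.kg_subgraph <- function(x, ...) {
  cat(sprintf("<kg_subgraph> %d node(s), %d relationship(s)\n",
              nrow(x$nodes), length(x$relationships)))
  if (nrow(x$nodes) > 0) print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' Count edges of given types in a subgraph
#' @param subgraph A `kg_subgraph`.
#' @param type Character vector of relationship types.
#' @return Integer count.
#' @export
subgraph_edge_count <- function(subgraph, type) {
  sum(vapply(subgraph$relationships, function(r) r$type %in% type,
             logical(1)))
}

#' Descendants of a chemical class in the ontology
#'
#' Recursively collects all chemicals below the parent node(s) with the
#' given name, traversing all nine chemical-chemical relation types
#' against their stored child-to-parent direction. With `require_formula`
#' only rows carrying a specific molecular formula are returned, excluding
#' generic class nodes. Cycles terminate via a visited set; rows are
#' distinct on the full (name, formula, chebi, inchi) tuple.
#'
#' @param graph A `kgraph`.
#' @param parent_name Name of the parent chemical class, e.g.
#'   `"flavonoid"`.
#' @param require_formula Drop rows without a formula property.
#' @return Data frame with columns `name`, `formula`, `chebi`, `inchi`;
#'   the root keys used are attached as attribute `"roots"`.
#' @export
descendant_chemicals <- function(graph, parent_name,
                                 require_formula = TRUE) {
  roots <- character()
  for (id in graph_nodes(graph, "Chemical")) {
    chem <- get_node(graph, "Chemical", id)
    if (identical(chem$name, parent_name)) roots <- c(roots, id)
  }
  rels <- graph_relationships(graph, CHEMICAL_RELATION_TYPES)
  rels <- rels[rels$from_label == "Chemical", , drop = FALSE]
  children_of <- split(rels$from_id, rels$to_id)

  visited <- character()
  frontier <- roots
  while (length(frontier) > 0) {
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(visited, roots))
    visited <- c(visited, nxt)
    frontier <- nxt
  }

  rows <- lapply(visited, function(id) {
    chem <- get_node(graph, "Chemical", id)
    data.frame(name = chem$name %||% NA_character_,
               formula = chem$formula %||% NA_character_,
               chebi = unname(chem$xrefs["chebi"]) %||% NA_character_,
               inchi = chem$inchi %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0)
    data.frame(name = character(), formula = character(),
               chebi = character(), inchi = character(),
               stringsAsFactors = FALSE)
  else unique(do.call(rbind, rows))
  if (require_formula) out <- out[!is.na(out$formula), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "roots") <- roots
  out
}

#' Metabolites of a taxon within a monoisotopic-mass window
#'
#' Chemicals connected to the taxon through the pattern Chemical
#' <-has_reactant- Reaction -catalysed_by-> Enzyme <-expresses- Organism
#' -is_a-> Organism(taxon), with stored monoisotopic mass strictly inside
#' `(mass_min, mass_max)`. `has_cofactor` edges are excluded, so currency
#' metabolites do not leak into the metabolome. The `is_a` hop is one
#' level by default; `transitive = TRUE` follows the taxonomy upwards so
#' deeper strain hierarchies also match.
#'
#' @param graph A `kgraph`.
#' @param taxon_id Parent taxon id (e.g. `"562"` for a species whose
#'   strains are its is_a children).
#' @param mass_min,mass_max Exclusive mass bounds in Da
#'   (`mass_min < mass_max`).
#' @param transitive Follow `is_a` chains beyond one hop.
#' @return Data frame with columns `name`, `monoisotopic_mass`,
#'   `formula`, `charge`, distinct rows.
#' @export
taxon_metabolome <- function(graph, taxon_id, mass_min, mass_max,
                             transitive = FALSE) {
  if (!(mass_min < mass_max))
    kg_validation_error("mass_min must be < mass_max")
  rels <- graph_relationships(graph)
  isa <- rels[rels$type == "is_a" & rels$from_label == "Organism", ,
              drop = FALSE]
  children <- isa$from_id[isa$to_id == taxon_id]
  if (transitive) {
    repeat {
      more <- setdiff(isa$from_id[isa$to_id %in% children], children)
      if (length(more) == 0) break
      children <- c(children, more)
    }
  }
  if (length(children) == 0) return(empty_metabolome())

  expr <- rels[rels$type == "expresses" & rels$from_id %in% children, ,
               drop = FALSE]
  enzymes <- unique(expr$to_id)
  cat_by <- rels[rels$type == "catalysed_by" & rels$to_id %in% enzymes, ,
                 drop = FALSE]
  rxns <- unique(cat_by$from_id)
  has_r <- rels[rels$type == "has_reactant" & rels$from_id %in% rxns, ,
                drop = FALSE]
  chems <- unique(has_r$to_id)

  rows <- list()
  for (id in chems) {
    chem <- get_node(graph, "Chemical", id)
    m <- chem$monoisotopic_mass
    if (is.null(m) || is.na(m)) next
    if (m > mass_min && m < mass_max)
      rows[[length(rows) + 1L]] <- data.frame(
        name = chem$name %||% NA_character_,
        monoisotopic_mass = m,
        formula = chem$formula %||% NA_character_,
        charge = chem$charge %||% NA_integer_,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_metabolome())
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

empty_metabolome <- function() {
  data.frame(name = character(), monoisotopic_mass = numeric(),
             formula = character(), charge = integer(),
             stringsAsFactors = FALSE)
}

#' Shortest stoichiometry-directed pathways from host metabolites
#'
#' Finds the shortest alternating chemical/reaction pathways from any
#' metabolite native to the host organism (a chemical attached by
#' `has_reactant` to a reaction catalysed by an enzyme the host expresses)
#' to the target chemical. Only `has_reactant` edges are traversed
#' (cofactor edges are excluded, so currency metabolites cannot act as
#' short cuts); edges are traversed regardless of stored direction, with
#' reactant-to-product directionality enforced by the sign rule: every
#' pair of consecutive edge stoichiometries along the path must have a
#' negative product, both where the edges meet at a reaction (consumed in,
#' produced out) and where they meet at an intermediate chemical (produced
#' in, consumed out). Paths are simple (no repeated chemical or reaction).
#'
#' @param graph A `kgraph`.
#' @param host_taxon_id Host organism taxonomy id.
#' @param target_chemical_id Target chemical node key (must exist).
#' @param max_len Maximum number of reactions in a pathway.
#' @param all_shortest Return all minimum-length pathways (`TRUE`) or the
#'   lexicographically first (`FALSE`).
#' @param produced_only Restrict the native-metabolite source set to
#'   chemicals *produced* (positive stoichiometry) by host reactions;
#'   default treats any has_reactant attachment as native.
#' @return List of `kg_pathway` objects (possibly empty); a length-0
#'   pathway is returned when the target is itself a native metabolite.
#' @export
find_pathways <- function(graph, host_taxon_id, target_chemical_id,
                          max_len = 8L, all_shortest = TRUE,
                          produced_only = FALSE) {
  if (is.null(get_node(graph, "Chemical", target_chemical_id)))
    kg_validation_error(sprintf("target chemical '%s' does not exist",
                                target_chemical_id))
  if (max_len < 1) kg_validation_error("max_len must be >= 1")
  rels <- graph_relationships(graph)
  expr <- rels[rels$type == "expresses" & rels$from_id == host_taxon_id, ,
               drop = FALSE]
  cat_by <- rels[rels$type == "catalysed_by" &
                   rels$to_id %in% expr$to_id, , drop = FALSE]
  host_rxns <- unique(cat_by$from_id)
  hr <- rels[rels$type == "has_reactant", , drop = FALSE]
  src_edges <- hr[hr$from_id %in% host_rxns, , drop = FALSE]
  if (produced_only)
    src_edges <- src_edges[src_edges$stoichiometry > 0, , drop = FALSE]
  sources <- sort(unique(src_edges$to_id))

  if (target_chemical_id %in% sources)
    return(list(new_pathway(target_chemical_id, character(), numeric())))

  # Adjacency over has_reactant edges.
  by_chem <- split(seq_len(nrow(hr)), hr$to_id)
  by_rxn <- split(seq_len(nrow(hr)), hr$from_id)

  best_len <- Inf
  found <- list()
  dfs <- function(chem, last_sign, chems_path, rxns_path, signs_path) {
    depth <- length(rxns_path)
    if (depth + 1 > best_len || depth + 1 > max_len) return(invisible(NULL))
    for (ei in by_chem[[chem]] %||% integer()) {
      s1 <- hr$stoichiometry[ei]
      if (!is.na(last_sign) && !(s1 * last_sign < 0)) next
      rxn <- hr$from_id[ei]
      if (rxn %in% rxns_path) next
      for (ej in by_rxn[[rxn]] %||% integer()) {
        s2 <- hr$stoichiometry[ej]
        if (!(s2 * s1 < 0)) next
        nxt <- hr$to_id[ej]
        if (nxt %in% chems_path) next
        nc <- c(chems_path, nxt); nr <- c(rxns_path, rxn)
        nsg <- c(signs_path, s1, s2)
        if (nxt == target_chemical_id) {
          if (length(nr) < best_len) { best_len <<- length(nr); found <<- list() }
          if (length(nr) == best_len)
            found[[length(found) + 1L]] <<- new_pathway(nc, nr, nsg)
        } else {
          dfs(nxt, s2, nc, nr, nsg)
        }
      }
    }
    invisible(NULL)
  }
  for (s in sources) dfs(s, NA_real_, s, character(), numeric())

  if (length(found) == 0) return(list())
  keys <- vapply(found, function(p)
    paste(pathway_node_sequence(p), collapse = "\r"), character(1))
  found <- found[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  found <- found[order(keys)]
  if (!all_shortest && length(found) > 0) found <- found[1]
  found
}

new_pathway <- function(chems, rxns, signs) {
  structure(list(chemicals = chems, reactions = rxns,
                 signs = signs, length = length(rxns)),
            class = "kg_pathway")
}

#' Interleaved node sequence of a pathway
#' @param pathway A `kg_pathway`.
#' @return Character vector chemical, reaction, chemical, ...
#' @export
pathway_node_sequence <- function(pathway) {
  k <- pathway$length
  if (k == 0) return(pathway$chemicals)
  out <- character(2 * k + 1)
  out[seq(1, 2 * k + 1, by = 2)] <- pathway$chemicals
  out[seq(2, 2 * k, by = 2)] <- pathway$reactions
  out
}

#' @export
print.kg_pathway <- function(x, ...) {
  cat(sprintf("<kg_pathway> length %d: %s\n", x$length,
              paste(pathway_node_sequence(x), collapse = " -> ")))
  invisible(x)
}

#' Structural validity of a pathway
#'
#' Checks the pathway type invariants: alternating chemical/reaction
#' sequence shape, consecutive edge stoichiometries with negative
#' products, and length within `max_len`.
#'
#' @param pathway A `kg_pathway`.
#' @param max_len Maximum allowed length.
#' @return Logical scalar.
#' @export
validate_pathway <- function(pathway, max_len = 8L) {
  k <- pathway$length
  if (k > max_len) return(FALSE)
  if (length(pathway$chemicals) != k + 1) return(FALSE)
  if (length(pathway$reactions) != k) return(FALSE)
  if (length(pathway$signs) != 2 * k) return(FALSE)
  if (k == 0) return(TRUE)
  s <- pathway$signs
  all(s[-1] * s[-length(s)] < 0)
}

#' Enzymes and organisms along pathways
#'
#' For every reaction appearing in any of the given pathways, returns
#' every (catalysing enzyme, expressing organism) pair. Reactions with no
#' enzyme yield a row with empty enzyme and organism fields; enzymes
#' expressed by no organism yield a row with an empty organism field.
#'
#' @param graph A `kgraph`.
#' @param pathways List of `kg_pathway` objects from [find_pathways()] on
#'   the same graph.
#' @return Data frame with columns `reaction_id`, `enzyme_id`,
#'   `organism_taxonomy`.
#' @export
pathway_enzymes <- function(graph, pathways) {
  rxns <- unique(unlist(lapply(pathways, `[[`, "reactions")))
  proto <- data.frame(reaction_id = character(), enzyme_id = character(),
                      organism_taxonomy = character(),
                      stringsAsFactors = FALSE)
  if (length(rxns) == 0) return(proto)
  rels <- graph_relationships(graph)
  cat_by <- rels[rels$type == "catalysed_by", , drop = FALSE]
  expr <- rels[rels$type == "expresses", , drop = FALSE]
  rows <- list()
  for (r in rxns) {
    enzymes <- cat_by$to_id[cat_by$from_id == r]
    if (length(enzymes) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = r, enzyme_id = "", organism_taxonomy = "",
        stringsAsFactors = FALSE)
      next
    }
    for (e in unique(enzymes)) {
      orgs <- expr$from_id[expr$to_id == e]
      if (length(orgs) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction_id = r, enzyme_id = e, organism_taxonomy = "",
          stringsAsFactors = FALSE)
      } else {
        for (o in unique(orgs))
          rows[[length(rows) + 1L]] <- data.frame(
            reaction_id = r, enzyme_id = e, organism_taxonomy = o,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
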