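# The embedded labelled-property-graph store. Nodes are keyed per label
# (Organism by taxonomy id, Enzyme by UniProt accession, Reaction and
# Chemical by id); relationships are directed, typed, carry properties and
# deduplicate on the full (from, to, type, properties) tuple. Iteration
# order is insertion order so that exports are reproducible.

# Allowed (From, To) label signatures per relationship type.
REL_SIGNATURES <- list(
  is_a = list(c("Organism", "Organism"), c("Chemical", "Chemical")),
  expresses = list(c("Organism", "Enzyme")),
  catalysed_by = list(c("Reaction", "Enzyme")),
  has_reactant = list(c("Reaction", "Chemical")),
  has_cofactor = list(c("Reaction", "Chemical")),
  has_functional_parent = list(c("Chemical", "Chemical")),
  has_parent_hydride = list(c("Chemical", "Chemical")),
  has_part = list(c("Chemical", "Chemical")),
  is_conjugate_acid_of = list(c("Chemical", "Chemical")),
  is_conjugate_base_of = list(c("Chemical", "Chemical")),
  is_enantiomer_of = list(c("Chemical", "Chemical")),
  is_substituent_group_from = list(c("Chemical", "Chemical")),
  is_tautomer_of = list(c("Chemical", "Chemical"))
)

# The nine chemical-to-chemical ontology relation types.
CHEMICAL_RELATION_TYPES <- c(
  "has_functional_parent", "has_parent_hydride", "has_part", "is_a",
  "is_conjugate_acid_of", "is_conjugate_base_of", "is_enantiomer_of",
  "is_substituent_group_from", "is_tautomer_of"
)

#' Create an empty knowledge graph
#'
#' The graph is an in-memory labelled property graph holding Organism,
#' Enzyme, Reaction and Chemical nodes plus directed typed relationships.
#' It is a mutable environment: [upsert_node()] and [add_relationship()]
#' modify it in place.
#'
#' @return An object of class `"kgraph"`.
#' @export
kgraph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- stats::setNames(
    lapply(NODE_LABELS, function(x) list()), NODE_LABELS)
  g$rels <- list()
  g$rel_index <- new.env(hash = TRUE, parent = emptyenv())
  class(g) <- "kgraph"
  g
}

#' @export
print.kgraph <- function(x, ...) {
  cat("<kgraph>\n")
  for (lab in NODE_LABELS)
    cat(sprintf("  %-9s %d\n", lab, length(x$nodes[[lab]])))
  cat(sprintf("  relationships %d\n", length(x$rels)))
  invisible(x)
}

#' Number of nodes in a graph
#' @param graph A `kgraph`.
#' @param label Optional node label to restrict the count to.
#' @return Integer count.
#' @export
node_count <- function(graph, label = NULL) {
  if (is.null(label)) return(sum(lengths(graph$nodes)))
  check_label(label)
  length(graph$nodes[[label]])
}

#' Number of relationships in a graph
#' @param graph A `kgraph`.
#' @param type Optional relationship type to restrict the count to.
#' @return Integer count.
#' @export
relationship_count <- function(graph, type = NULL) {
  if (is.null(type)) return(length(graph$rels))
  sum(vapply(graph$rels, function(r) r$type == type, logical(1)))
}

#' Fetch a node's entity record
#' @param graph A `kgraph`.
#' @param label Node label.
#' @param key Node key.
#' @return The entity record, or `NULL` if absent.
#' @export
get_node <- function(graph, label, key) {
  check_label(label)
  graph$nodes[[label]][[key]]
}

#' All node keys of one label, in insertion order
#' @param graph A `kgraph`.
#' @param label Node label.
#' @return Character vector of keys.
#' @export
graph_nodes <- function(graph, label) {
  check_label(label)
  names(graph$nodes[[label]])
}

check_label <- function(label) {
  if (!is.character(label) || length(label) != 1 ||
      !(label %in% NODE_LABELS))
    kg_schema_error(sprintf("unknown node label '%s' (must be one of %s)",
                            paste(label, collapse = ","),
                            paste(NODE_LABELS, collapse = ", ")))
  invisible(label)
}

#' Insert or merge a node
#'
#' Inserting a key that already exists merges the new record into the old
#' one: missing scalar properties are filled in (first-loaded value wins),
#' synonym lists, EC lists and cross-reference maps are unioned. Conflicting
#' scalars keep the stored value (source-precedence conflict resolution is
#' handled at merge time by [merge_entities()], before upserting).
#'
#' @param graph A `kgraph` (modified in place).
#' @param label One of `"Organism"`, `"Enzyme"`, `"Reaction"`, `"Chemical"`.
#' @param entity An entity record (see [chemical_entity()] and friends), or
#'   a plain named list with the same fields.
#' @return The node key, invisibly.
#' @export
upsert_node <- function(graph, label, entity) {
  check_label(label)
  if (!inherits(entity, "kg_entity")) entity <- coerce_entity(entity, label)
  if (entity_label(entity) != label)
    kg_schema_error(sprintf("entity of class %s cannot be upserted as %s",
                            class(entity)[1], label))
  validate_entity(entity, label)
  key <- entity_key(entity, label)
  old <- graph$nodes[[label]][[key]]
  if (!is.null(old)) entity <- merge_records(old, entity)
  graph$nodes[[label]][[key]] <- entity
  invisible(key)
}

coerce_entity <- function(entity, label) {
  if (!is.list(entity)) kg_validation_error("entity must be a list")
  tryCatch(
    switch(label,
      Chemical = do.call(chemical_entity, entity),
      Reaction = do.call(reaction_entity, entity),
      Enzyme = do.call(enzyme_entity, entity),
      Organism = do.call(organism_entity, entity)),
    kg_error = function(e) stop(e),
    error = function(e)
      kg_validation_error(sprintf("invalid %s record: %s", label,
                                  conditionMessage(e))))
}

# First-loaded-wins property merge used by idempotent upserts.
merge_records <- function(old, new) {
  for (f in names(new)) {
    if (f %in% c("names")) {
      extra <- setdiff(c(new$names, new$name), c(old$names, old$name))
      old$names <- c(old$names, extra[!is.null(extra) & nzchar(extra)])
    } else if (f %in% c("ec", "ec_code")) {
      old[[f]] <- union(old[[f]], new[[f]])
    } else if (f == "xrefs") {
      add <- setdiff(names(new$xrefs), names(old$xrefs))
      old$xrefs <- c(old$xrefs, new$xrefs[add])
    } else if (f == "participants") {
      if (nrow(old$participants) == 0) old$participants <- new$participants
    } else if (is.null(old[[f]]) ||
               (length(old[[f]]) == 1 && is.na(old[[f]]))) {
      old[[f]] <- new[[f]]
    }
  }
  old
}

#' Construct a relationship record
#'
#' @param from_label,from_id From endpoint (label and node key).
#' @param type Relationship type (e.g. `"expresses"`, `"has_reactant"`).
#' @param to_label,to_id To endpoint.
#' @param properties Named list of edge properties (`stoichiometry` on
#'   reaction-chemical edges, `source` on expresses/catalysed_by edges).
#' @return A list of class `"kg_relationship"`.
#' @export
relationship <- function(from_label, from_id, type, to_label, to_id,
                         properties = list()) {
  structure(list(from_label = from_label, from_id = as.character(from_id),
                 type = type, to_label = to_label,
                 to_id = as.character(to_id),
                 properties = properties),
            class = "kg_relationship")
}

rel_key <- function(rel) {
  props <- rel$properties
  pk <- if (length(props) == 0) "" else {
    o <- order(names(props))
    paste(names(props)[o], vapply(props[o], as.character, character(1)),
          sep = "=", collapse = ";")
  }
  paste(rel$from_label, rel$from_id, rel$type, rel$to_label, rel$to_id, pk,
        sep = "\r")
}

#' Add a directed, typed relationship
#'
#' Both endpoints must already exist and the (From, To) labels must match
#' the type's signature. Fully identical relationships (same endpoints,
#' type and properties) collapse to one; identical triples that differ in
#' a property such as `source` are kept as distinct edges so provenance is
#' preserved.
#'
#' @param graph A `kgraph` (modified in place).
#' @param rel A [relationship()] record.
#' @return `TRUE` if the edge was added, `FALSE` if it was a duplicate,
#'   invisibly.
#' @export
add_relationship <- function(graph, rel) {
  if (!inherits(rel, "kg_relationship"))
    kg_validation_error("rel must be built with relationship()")
  sig <- REL_SIGNATURES[[rel$type]]
  if (is.null(sig))
    kg_schema_error(sprintf("unknown relationship type '%s'", rel$type))
  ok <- any(vapply(sig, function(s)
    identical(s, c(rel$from_label, rel$to_label)), logical(1)))
  if (!ok)
    kg_schema_error(sprintf(
      "relationship %s cannot connect %s to %s", rel$type,
      rel$from_label, rel$to_label))
  if (is.null(get_node(graph, rel$from_label, rel$from_id)))
    kg_validation_error(sprintf("dangling endpoint: %s '%s' does not exist",
                                rel$from_label, rel$from_id))
  if (is.null(get_node(graph, rel$to_label, rel$to_id)))
    kg_validation_error(sprintf("dangling endpoint: %s '%s' does not exist",
                                rel$to_label, rel$to_id))
  key <- rel_key(rel)
  if (!is.null(graph$rel_index[[key]])) return(invisible(FALSE))
  graph$rels[[length(graph$rels) + 1L]] <- rel
  graph$rel_index[[key]] <- length(graph$rels)
  invisible(TRUE)
}

#' Relationships as a data frame
#'
#' Flattens the relationship multiset into a data frame with one row per
#' edge; `stoichiometry` and `source` properties become columns (`NA` when
#' absent).
#'
#' @param graph A `kgraph`.
#' @param type Optional type filter (character vector).
#' @return Data frame with columns `from_label`, `from_id`, `type`,
#'   `to_label`, `to_id`, `stoichiometry`, `source`.
#' @export
graph_relationships <- function(graph, type = NULL) {
  rels <- graph$rels
  if (!is.null(type))
    rels <- Filter(function(r) r$type %in% type, rels)
  n <- length(rels)
  getp <- function(r, p, cast)
    if (is.null(r$properties[[p]])) cast(NA) else cast(r$properties[[p]])
  data.frame(
    from_label = vapply(rels, `[[`, character(1), "from_label"),
    from_id = vapply(rels, `[[`, character(1), "from_id"),
    type = vapply(rels, `[[`, character(1), "type"),
    to_label = vapply(rels, `[[`, character(1), "to_label"),
    to_id = vapply(rels, `[[`, character(1), "to_id"),
    stoichiometry = vapply(rels, getp, numeric(1), "stoichiometry",
                           as.numeric),
    source = vapply(rels, getp, character(1), "source", as.character),
    stringsAsFactors = FALSE
  )[seq_len(n), , drop = FALSE]
}

# Replace the whole relationship list (used when rewiring or retyping
# edges); rebuilds the dedup index and collapses any duplicates created by
# the rewrite.
set_relationships <- function(graph, rels) {
  graph$rels <- list()
  graph$rel_index <- new.env(hash = TRUE, parent = emptyenv())
  for (r in rels) {
    key <- rel_key(r)
    if (is.null(graph$rel_index[[key]])) {
      graph$rels[[length(graph$rels) + 1L]] <- r
      graph$rel_index[[key]] <- length(graph$rels)
    }
  }
  invisible(graph)
}

#' Structural validation of a knowledge graph
#'
#' Full-scan checks of the model invariants: every relationship endpoint
#' resolves to an existing node, every (From, type, To) triple is in the
#' schema's signature set, and organism parent pointers form a tree with
#' exactly one root.
#'
#' @param graph A `kgraph`.
#' @return `TRUE` invisibly; signals a condition on violation.
#' @export
validate_graph <- function(graph) {
  for (r in graph$rels) {
    if (is.null(get_node(graph, r$from_label, r$from_id)) ||
        is.null(get_node(graph, r$to_label, r$to_id)))
      kg_validation_error(sprintf("dangling relationship %s %s->%s",
                                  r$type, r$from_id, r$to_id))
    sig <- REL_SIGNATURES[[r$type]]
    if (is.null(sig) || !any(vapply(sig, function(s)
      identical(s, c(r$from_label, r$to_label)), logical(1))))
      kg_schema_error(sprintf("signature violation: %s %s->%s",
                              r$from_label, r$type, r$to_label))
  }
  orgs <- graph$nodes$Organism
  if (length(orgs) > 0) {
    isa <- graph_relationships(graph, "is_a")
    isa <- isa[isa$from_label == "Organism", , drop = FALSE]
    parent <- stats::setNames(isa$to_id, isa$from_id)
    roots <- setdiff(names(orgs), names(parent))
    if (length(roots) != 1)
      kg_validation_error(sprintf("taxonomy must have exactly one root (found %d)",
                                  length(roots)))
    for (start in names(parent)) {
      seen <- character()
      cur <- start
      while (cur %in% names(parent)) {
        if (cur %in% seen)
          kg_validation_error("cycle in organism taxonomy")
        seen <- c(seen, cur)
        cur <- unname(parent[[cur]])
      }
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Node and relationship summary statistics
#'
#' Per-label node counts, and for every ordered label pair connected by at
#' least one relationship, the number of row-label nodes carrying such a
#' relationship together with the coverage percentage (100 x carriers /
#' label size). Both orientations of a stored direction are reported (an
#' `expresses` edge contributes to both the Organism-Enzyme and the
#' Enzyme-Organism rows); same-label pairs report the stored (From-side)
#' orientation only, so for example a taxonomy root without a parent
#' reduces Organism-Organism coverage.
#'
#' @param graph A `kgraph`.
#' @return List of class `"kg_summary"` with elements `nodes` (data frame
#'   `label`, `count`) and `relationships` (data frame `from_label`,
#'   `to_label`, `n_relationships`, `n_nodes_with`, `coverage_pct`).
#' @export
summary_stats <- function(graph) {
  nodes <- data.frame(
    label = NODE_LABELS,
    count = vapply(NODE_LABELS, function(l) length(graph$nodes[[l]]),
                   integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  nodes <- nodes[nodes$count > 0, , drop = FALSE]

  rels <- graph_relationships(graph)
  if (nrow(rels) == 0) {
    out <- list(nodes = nodes,
                relationships = data.frame(
                  from_label = character(), to_label = character(),
                  n_relationships = integer(), n_nodes_with = integer(),
                  coverage_pct = numeric(), stringsAsFactors = FALSE))
    class(out) <- "kg_summary"
    return(out)
  }

  carriers <- new.env(parent = emptyenv())  # "A|B" -> char vector of A keys
  edge_n <- new.env(parent = emptyenv())    # "A|B" -> stored A->B edge count
  addc <- function(k, id) assign(k, union(get0(k, carriers, ifnotfound =
                                                 character()), id), carriers)
  for (i in seq_len(nrow(rels))) {
    fl <- rels$from_label[i]; tl <- rels$to_label[i]
    k <- paste(fl, tl, sep = "|")
    assign(k, (get0(k, edge_n, ifnotfound = 0L)) + 1L, edge_n)
    addc(k, rels$from_id[i])
    if (fl != tl) addc(paste(tl, fl, sep = "|"), rels$to_id[i])
  }
  pairs <- sort(ls(carriers))
  rows <- lapply(pairs, function(k) {
    ab <- strsplit(k, "|", fixed = TRUE)[[1]]
    n_with <- length(get(k, carriers))
    n_lab <- length(graph$nodes[[ab[1]]])
    # Edge count between the two labels, either stored direction.
    ne <- get0(k, edge_n, ifnotfound = 0L) +
      if (ab[1] != ab[2]) get0(paste(ab[2], ab[1], sep = "|"), edge_n,
                               ifnotfound = 0L) else 0L
    data.frame(from_label = ab[1], to_label = ab[2], n_relationships = ne,
               n_nodes_with = n_with,
               coverage_pct = 100 * n_with / n_lab,
               stringsAsFactors = FALSE)
  })
  out <- list(nodes = nodes, relationships = do.call(rbind, rows))
  class(out) <- "kg_summary"
  out
}

#' @export
print.kg_summary <- function(x, ...) {
  cat("Nodes:\n")
  print(x$nodes, row.names = FALSE)
  cat("\nRelationships (coverage = % of row-label nodes carrying one):\n")
  r <- x$relationships
  if (nrow(r) > 0) r$coverage_pct <- round(r$coverage_pct, 3)
  print(r, row.names = FALSE)
  invisible(x)
}
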