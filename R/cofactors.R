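# Cofactor classification. A reaction participant is annotated as a
# cofactor rather than a reactant when it is a low-molecular-mass species
# (< 44 Da, which also captures CO2 at 43.9898 Da under the strict reading)
# or one half of a frequently co-occurring opposite-sign metabolite pair
# such as ATP/ADP. Cofactor edges are excluded from pathway traversal, so
# this classification is what prevents "short cut" paths through currency
# metabolites.

#' Low-molecular-mass cofactor test
#'
#' `TRUE` iff the chemical's monoisotopic mass is strictly below 44 Da. The
#' stored mass property is used when present, otherwise the mass is
#' computed from the formula; chemicals with neither (generic class nodes)
#' are never low-mass cofactors.
#'
#' @param chemical A [chemical_entity()] record.
#' @param threshold Mass threshold in Da (default 44).
#' @return Logical scalar.
#' @export
is_low_mass_cofactor <- function(chemical, threshold = 44) {
  m <- chemical_mass(chemical)
  !is.na(m) && m < threshold
}

#' Detect frequently co-occurring opposite-sign chemical pairs
#'
#' A pair (a, b) is frequent when a appears with negative and b with
#' positive stoichiometry (or vice versa) in at least `min_pair_count`
#' reactions. Pairs co-occurring on the same side only do not count.
#'
#' @param reactions List of [reaction_entity()] records.
#' @param min_pair_count Minimum number of reactions (>= 2).
#' @return Data frame with columns `a`, `b` (unordered pair, `a < b`
#'   lexicographically) and `n_reactions`, ordered by decreasing count then
#'   pair id.
#' @export
detect_frequent_pairs <- function(reactions, min_pair_count) {
  if (!is.numeric(min_pair_count) || min_pair_count < 2)
    kg_validation_error("min_pair_count must be >= 2")
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (rxn in reactions) {
    p <- rxn$participants
    if (nrow(p) < 2) next
    neg <- unique(p$chemical_id[p$stoichiometry < 0])
    pos <- unique(p$chemical_id[p$stoichiometry > 0])
    keys <- character()
    for (a in neg) for (b in pos) {
      if (a == b) next
      keys <- c(keys, paste(sort(c(a, b)), collapse = "\r"))
    }
    for (k in unique(keys))  # each reaction counts a pair at most once
      assign(k, get0(k, counts, ifnotfound = 0L) + 1L, counts)
  }
  keys <- ls(counts)
  n <- vapply(keys, get, integer(1), envir = counts)
  keep <- n >= min_pair_count
  keys <- keys[keep]; n <- n[keep]
  ab <- do.call(rbind, c(list(matrix(character(), ncol = 2)),
                         lapply(strsplit(keys, "\r", fixed = TRUE), rbind)))
  out <- data.frame(a = ab[, 1], b = ab[, 2], n_reactions = as.integer(n),
                    stringsAsFactors = FALSE)
  out[order(-out$n_reactions, out$a, out$b), , drop = FALSE]
}

#' Default frequent-pair threshold
#'
#' "Frequently occurring" is operationalised as co-occurrence in at least
#' `max(2, ceiling(0.05 * n_reactions))` reactions, computed at load time.
#'
#' @param n_reactions Number of reactions in the network.
#' @return Integer threshold.
#' @export
default_min_pair_count <- function(n_reactions) {
  max(2L, as.integer(ceiling(0.05 * n_reactions)))
}

#' Annotate reaction participants as cofactors
#'
#' Relabels `has_reactant` edges to `has_cofactor` for participants that
#' are low-mass cofactors, or whose frequent-pair partner participates in
#' the same reaction with opposite sign (both pair members are relabelled).
#' Stoichiometries and the total reaction-chemical edge count are
#' preserved; only the edge type (and participant role) changes.
#'
#' @param graph A `kgraph` (modified in place).
#' @param min_pair_count Frequent-pair threshold; default
#'   [default_min_pair_count()] of the graph's reaction count.
#' @return Number of relabelled edges, invisibly.
#' @export
annotate_cofactors <- function(graph,
                               min_pair_count = default_min_pair_count(
                                 node_count(graph, "Reaction"))) {
  reactions <- graph$nodes$Reaction
  pairs <- detect_frequent_pairs(reactions, min_pair_count)
  pair_key <- paste(pairs$a, pairs$b, sep = "\r")

  cof_of <- function(rxn) {
    p <- rxn$participants
    if (nrow(p) == 0) return(character())
    low <- vapply(p$chemical_id, function(id) {
      chem <- get_node(graph, "Chemical", id)
      !is.null(chem) && is_low_mass_cofactor(chem)
    }, logical(1))
    in_pair <- rep(FALSE, nrow(p))
    if (length(pair_key) > 0) {
      neg <- p$chemical_id[p$stoichiometry < 0]
      pos <- p$chemical_id[p$stoichiometry > 0]
      for (i in seq_len(nrow(p))) {
        partners <- if (p$stoichiometry[i] < 0) pos else neg
        for (q in partners) {
          k <- paste(sort(c(p$chemical_id[i], q)), collapse = "\r")
          if (k %in% pair_key) { in_pair[i] <- TRUE; break }
        }
      }
    }
    unique(p$chemical_id[low | in_pair])
  }

  cof_sets <- lapply(reactions, cof_of)
  names(cof_sets) <- names(reactions)

  n_relabelled <- 0L
  rels <- graph$rels
  for (i in seq_along(rels)) {
    r <- rels[[i]]
    if (r$type != "has_reactant") next
    if (r$to_id %in% (cof_sets[[r$from_id]] %||% character())) {
      r$type <- "has_cofactor"
      rels[[i]] <- r
      n_relabelled <- n_relabelled + 1L
    }
  }
  set_relationships(graph, rels)

  # Keep participant roles on the reaction records in step with the edges.
  for (id in names(reactions)) {
    rxn <- reactions[[id]]
    if (nrow(rxn$participants) == 0) next
    rxn$participants$role <-
      ifelse(rxn$participants$chemical_id %in% cof_sets[[id]],
             "cofactor", "reactant")
    graph$nodes$Reaction[[id]] <- rxn
  }
  invisible(n_relabelled)
}
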