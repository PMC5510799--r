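# Independent brute-force oracles. These deliberately share no code with
# the implementation: closures are computed by matrix powers, pathway
# enumeration by naive recursion over edge rows, balancing optima by full
# grid enumeration.

# All sign-valid simple alternating paths of minimum length, as sorted
# node-sequence strings ("chem\rrxn\rchem...").
oracle_pathways <- function(graph, host, target, max_len = 8L) {
  rels <- graph_relationships(graph)
  hr <- rels[rels$type == "has_reactant", , drop = FALSE]
  expr <- rels[rels$type == "expresses" & rels$from_id == host, ,
               drop = FALSE]
  cb <- rels[rels$type == "catalysed_by" & rels$to_id %in% expr$to_id, ,
             drop = FALSE]
  sources <- sort(unique(hr$to_id[hr$from_id %in% unique(cb$from_id)]))
  if (length(sources) == 0) return(character())
  if (target %in% sources) return(target)

  hits <- list()
  grow <- function(nodes, signs, used_r, used_c) {
    cur <- nodes[length(nodes)]
    if (length(used_r) >= max_len) return(invisible(NULL))
    for (i in which(hr$to_id == cur)) {
      s1 <- hr$stoichiometry[i]
      if (length(signs) > 0 && !(s1 * signs[length(signs)] < 0)) next
      r <- hr$from_id[i]
      if (r %in% used_r) next
      for (j in which(hr$from_id == r)) {
        s2 <- hr$stoichiometry[j]
        if (!(s2 * s1 < 0)) next
        nxt <- hr$to_id[j]
        if (nxt %in% used_c) next
        nn <- c(nodes, r, nxt)
        if (nxt == target) {
          hits[[length(hits) + 1L]] <<- nn
        } else {
          grow(nn, c(signs, s1, s2), c(used_r, r), c(used_c, nxt))
        }
      }
    }
    invisible(NULL)
  }
  for (s in sources) grow(s, numeric(), character(), s)
  if (length(hits) == 0) return(character())
  lens <- vapply(hits, length, integer(1))
  hits <- hits[lens == min(lens)]
  sort(unique(vapply(hits, paste, character(1), collapse = "\r")))
}

# Transitive descendants of a set of roots over chemical-chemical edges,
# by boolean matrix powers.
oracle_descendant_keys <- function(graph, roots) {
  keys <- graph_nodes(graph, "Chemical")
  n <- length(keys)
  rels <- graph_relationships(graph)
  rels <- rels[rels$from_label == "Chemical" & rels$to_label == "Chemical", ,
               drop = FALSE]
  A <- matrix(FALSE, n, n, dimnames = list(keys, keys))
  for (i in seq_len(nrow(rels)))
    A[rels$to_id[i], rels$from_id[i]] <- TRUE   # parent -> child
  reach <- A
  prev <- matrix(FALSE, n, n)
  while (!identical(reach, prev)) {
    prev <- reach
    reach <- reach | ((reach %*% A) > 0)
  }
  hit <- colSums(reach[roots, , drop = FALSE]) > 0
  setdiff(keys[hit], roots)
}

# Per-reaction census of opposite-sign pair co-occurrence.
oracle_frequent_pairs <- function(reactions, min_count) {
  pairs <- character()
  chems <- unique(unlist(lapply(reactions, function(r)
    r$participants$chemical_id)))
  if (length(chems) < 2) return(character())
  combos <- utils::combn(sort(chems), 2)
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    n <- 0L
    for (r in reactions) {
      p <- r$participants
      sa <- p$stoichiometry[p$chemical_id == a]
      sb <- p$stoichiometry[p$chemical_id == b]
      if (length(sa) == 1 && length(sb) == 1 && sa * sb < 0) n <- n + 1L
    }
    if (n >= min_count) pairs <- c(pairs, paste(a, b, sep = "|"))
  }
  sort(pairs)
}

# Lexicographic optimum (deviation, added total) of the balancing problem
# by full grid enumeration; NULL when infeasible.
oracle_balance_optimum <- function(participants, chemicals,
                                   addable = default_addable_species(),
                                   max_coef = 3L) {
  comp <- function(chem) {
    ev <- parse_formula(chem$formula)
    c(ev, charge = chem$charge)
  }
  comps <- lapply(participants$chemical_id, function(id)
    comp(chemicals[[id]]))
  addable <- Filter(function(s)
    !(s$id %in% participants$chemical_id), addable)
  acomps <- lapply(addable, function(s)
    c(parse_formula(s$formula), charge = s$charge))
  elems <- unique(unlist(lapply(c(comps, acomps), names)))
  vec <- function(cv) {
    out <- stats::setNames(numeric(length(elems)), elems)
    out[names(cv)] <- cv
    out
  }
  M <- vapply(comps, vec, numeric(length(elems)))
  A <- if (length(acomps) > 0)
    vapply(acomps, vec, numeric(length(elems)))
  else matrix(0, nrow = length(elems), ncol = 0)
  sides <- sign(participants$stoichiometry)
  old <- abs(participants$stoichiometry)
  n <- length(old)
  grids <- c(rep(list(1:max_coef), n),
             rep(list(seq(-max_coef, max_coef)), length(acomps)))
  combos <- as.matrix(do.call(expand.grid, grids))
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    mags <- combos[r, seq_len(n)]
    adds <- if (length(acomps) > 0) combos[r, -seq_len(n)] else numeric(0)
    resid <- as.numeric(M %*% (sides * mags)) +
      (if (length(adds) > 0) as.numeric(A %*% adds) else 0)
    if (any(abs(resid) > 1e-9)) next
    obj <- c(sum(abs(mags - old)), sum(abs(adds)))
    if (is.null(best) || obj[1] < best[1] ||
        (obj[1] == best[1] && obj[2] < best[2])) best <- obj
  }
  best
}

# Structural graph equality under canonical ordering (node keys sorted,
# entity fields compared order-independently, relationships as a sorted
# multiset of strings).
graph_equal <- function(g1, g2, tol = 1e-8) {
  canon_entity <- function(e) {
    e <- unclass(e)
    e <- e[order(names(e))]
    e <- Filter(function(v) !is.null(v) &&
                  !(is.data.frame(v) && nrow(v) == 0) &&
                  !(length(v) == 1 && !is.data.frame(v) && is.na(v)) &&
                  length(v) > 0, e)
    if (!is.null(e$xrefs)) e$xrefs <- e$xrefs[order(names(e$xrefs))]
    if (!is.null(e$names)) e$names <- sort(e$names)
    if (!is.null(e$participants)) {
      p <- e$participants
      e$participants <- p[order(p$chemical_id, p$stoichiometry), ,
                          drop = FALSE]
      rownames(e$participants) <- NULL
    }
    e
  }
  num_eq <- function(a, b) is.numeric(a) && is.numeric(b) &&
    length(a) == length(b) && all(abs(a - b) < tol)
  fields_eq <- function(a, b) {
    if (!identical(sort(names(a)), sort(names(b)))) return(FALSE)
    for (f in names(a)) {
      if (identical(a[[f]], b[[f]])) next
      if (num_eq(a[[f]], b[[f]])) next
      if (is.data.frame(a[[f]]) && isTRUE(all.equal(a[[f]], b[[f]],
                                                    check.attributes = FALSE)))
        next
      return(FALSE)
    }
    TRUE
  }
  for (label in c("Organism", "Enzyme", "Reaction", "Chemical")) {
    k1 <- sort(graph_nodes(g1, label)); k2 <- sort(graph_nodes(g2, label))
    if (!identical(k1, k2)) return(FALSE)
    for (k in k1) {
      if (!fields_eq(canon_entity(get_node(g1, label, k)),
                     canon_entity(get_node(g2, label, k))))
        return(FALSE)
    }
  }
  rel_str <- function(g) {
    df <- graph_relationships(g)
    sort(paste(df$from_label, df$from_id, df$type, df$to_label, df$to_id,
               df$stoichiometry, df$source))
  }
  identical(rel_str(g1), rel_str(g2))
}
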