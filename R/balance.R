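# Reaction mass/charge balancing. A reaction is balanced when, over its
# signed integer stoichiometries, every element and the total charge sum to
# zero. Unbalanced reactions are repaired by a minimal-perturbation integer
# search: existing participants may change magnitude (never side, never to
# zero) and a configurable set of addable species (by default protons and
# water, the species most often missing from source reaction definitions)
# may be introduced on either side. The objective is lexicographic: first
# minimise the total deviation from the original stoichiometries, then the
# total amount of added species, with ties broken in favour of protons over
# water and smaller total coefficients. Reaction participant lists are
# small, so the search is a bounded exact enumeration over deviation
# budgets with an exact linear solve for the added-species coefficients.

#' Default addable species for rebalancing
#'
#' Protons (H, charge +1) and water (H2O, charge 0), each addable on
#' either side of a reaction.
#'
#' @return List of species descriptors (`id`, `formula`, `charge`).
#' @export
default_addable_species <- function() {
  list(list(id = "H+", formula = "H", charge = 1L),
       list(id = "H2O", formula = "H2O", charge = 0L))
}

# Element-and-charge composition vector of a chemical; NULL when formula or
# charge is missing (the "unknown" signal).
composition_of <- function(chem) {
  if (is.null(chem) || is.null(chem$formula) || is.null(chem$charge) ||
      is.na(chem$charge)) return(NULL)
  ev <- tryCatch(parse_formula(chem$formula), kg_error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  c(ev, charge = as.integer(chem$charge))
}

# Stack participant compositions into a matrix (rows = components, cols =
# participants). Returns NULL if any composition is unknown.
composition_matrix <- function(chem_ids, chemicals) {
  comps <- lapply(chem_ids, function(id) composition_of(chemicals[[id]]))
  if (any(vapply(comps, is.null, logical(1)))) return(NULL)
  elems <- unique(unlist(lapply(comps, names)))
  m <- vapply(comps, function(cv) {
    out <- stats::setNames(numeric(length(elems)), elems)
    out[names(cv)] <- cv
    out
  }, numeric(length(elems)))
  matrix(m, nrow = length(elems), dimnames = list(elems, chem_ids))
}

#' Verify element and charge conservation
#'
#' `TRUE` iff for every element the stoichiometry-weighted counts sum to
#' zero and the stoichiometry-weighted charges sum to zero. An empty
#' participant list is vacuously balanced. If any participant's formula or
#' charge is unknown the answer is `NA` (the "unknown" signal), never
#' `FALSE`.
#'
#' @param participants Participant data frame (`chemical_id`,
#'   `stoichiometry`, `role`).
#' @param chemicals Named list of [chemical_entity()] records keyed by id.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
verify_balance <- function(participants, chemicals) {
  if (nrow(participants) == 0) return(TRUE)
  M <- composition_matrix(participants$chemical_id, chemicals)
  if (is.null(M)) return(NA)
  resid <- as.numeric(M %*% participants$stoichiometry)
  all(abs(resid) < 1e-9)
}

# Solve for integer added-species coefficients x (signed: negative =
# consumed side) with A x = -residual, |x| <= max_coef. A has full column
# rank for the default proton/water set, giving a unique exact solution;
# degenerate species sets fall back to a small grid. Returns a list of
# candidate solutions (usually 0 or 1).
solve_additions <- function(A, residual, max_coef) {
  k <- ncol(A)
  if (k == 0) {
    if (all(abs(residual) < 1e-9)) return(list(numeric(0)))
    return(list())
  }
  if (qr(A)$rank == k) {
    x <- qr.coef(qr(A), -residual)
    x[is.na(x)] <- 0
    xi <- round(x)
    if (max(abs(x - xi)) < 1e-6 && all(abs(xi) <= max_coef) &&
        all(abs(A %*% xi + residual) < 1e-9))
      return(list(as.numeric(xi)))
    return(list())
  }
  # Rank-deficient addable set: bounded grid (addable sets are tiny).
  grids <- rep(list(seq(-max_coef, max_coef)), k)
  combos <- as.matrix(expand.grid(grids))
  ok <- apply(combos, 1, function(x) all(abs(A %*% x + residual) < 1e-9))
  lapply(seq_len(sum(ok)), function(i) as.numeric(combos[which(ok)[i], ]))
}

# Enumerate magnitude vectors for existing participants at a given total
# deviation budget D (sum of |new - old| == D), respecting bounds
# 1 <= new <= max_coef. Calls fn(new_mags) for each.
enumerate_deviations <- function(old_mags, max_coef, D, fn) {
  n <- length(old_mags)
  rec <- function(i, left, acc) {
    if (i > n) {
      if (left == 0) fn(acc)
      return(invisible(NULL))
    }
    lo <- max(1L, old_mags[i] - left)
    hi <- min(max_coef, old_mags[i] + left)
    if (hi < lo) return(invisible(NULL))
    for (v in lo:hi) {
      d <- abs(v - old_mags[i])
      if (d <= left) rec(i + 1L, left - d, c(acc, v))
    }
  }
  rec(1L, D, integer(0))
  invisible(NULL)
}

#' Balance a reaction by minimal integer perturbation
#'
#' Searches for non-negative integer stoichiometry magnitudes for the
#' existing participants (each at least 1, each staying on its original
#' side) plus optional added species, subject to per-element and charge
#' conservation. The objective is lexicographic: minimise total deviation
#' from the original stoichiometries, then the total added-species amount,
#' preferring protons over water and smaller total coefficient sums.
#'
#' @param reaction A [reaction_entity()].
#' @param chemicals Named list of [chemical_entity()] records covering all
#'   participants.
#' @param config List with `addable_species` (see
#'   [default_addable_species()]) and `max_coefficient` (default 20); see
#'   [kg_config()].
#' @return A `kg_balance_result`: list with `status` (one of
#'   `"already_balanced"`, `"rebalanced"`, `"unbalanceable"`,
#'   `"unknown"`), `participants` (corrected data frame, including any
#'   added species), and `delta` (data frame `chemical_id`, `old_stoich`,
#'   `new_stoich` for every change).
#' @export
balance_reaction <- function(reaction, chemicals, config = kg_config()) {
  max_coef <- config$balance$max_coefficient %||% 20L
  addable <- config$balance$addable_species %||% default_addable_species()
  p <- reaction$participants
  result <- function(status, participants = p, delta = empty_delta())
    structure(list(status = status, participants = participants,
                   delta = delta), class = "kg_balance_result")

  if (nrow(p) == 0) return(result("already_balanced"))

  M <- composition_matrix(p$chemical_id, chemicals)
  if (is.null(M)) return(result("unknown"))

  ok <- all(abs(M %*% p$stoichiometry) < 1e-9)
  if (isTRUE(ok)) return(result("already_balanced"))

  # Addable species not already among the participants.
  addable <- Filter(function(s) !(s$id %in% p$chemical_id), addable)
  add_comps <- lapply(addable, function(s)
    c(parse_formula(s$formula), charge = as.integer(s$charge)))
  elems <- unique(c(rownames(M), unlist(lapply(add_comps, names))))
  Mx <- matrix(0, nrow = length(elems), ncol = ncol(M),
               dimnames = list(elems, colnames(M)))
  Mx[rownames(M), ] <- M
  A <- matrix(0, nrow = length(elems), ncol = length(addable),
              dimnames = list(elems, vapply(addable, `[[`, character(1),
                                            "id")))
  for (j in seq_along(add_comps)) A[names(add_comps[[j]]), j] <-
    add_comps[[j]]

  sides <- sign(p$stoichiometry)
  old_mags <- abs(p$stoichiometry)
  Dmax <- sum(pmax(max_coef - old_mags, old_mags - 1L))
  budget <- config$balance$search_budget %||% 200000L
  visited <- 0L
  best <- NULL   # list(add_total, water_pref, coef_total, mags, adds)

  water_amount <- function(adds) {
    wa <- 0
    for (j in seq_along(addable))
      if (identical(addable[[j]]$formula, "H2O")) wa <- wa + abs(adds[j])
    wa
  }

  for (D in 0:Dmax) {
    enumerate_deviations(old_mags, max_coef, D, function(mags) {
      visited <<- visited + 1L
      if (visited > budget) return(invisible(NULL))
      residual <- as.numeric(Mx %*% (sides * mags))
      for (adds in solve_additions(A, residual, max_coef)) {
        cand <- list(add_total = sum(abs(adds)),
                     water_pref = water_amount(adds),
                     coef_total = sum(mags) + sum(abs(adds)),
                     mags = mags, adds = adds)
        if (is.null(best) ||
            cand$add_total < best$add_total ||
            (cand$add_total == best$add_total &&
             (cand$water_pref < best$water_pref ||
              (cand$water_pref == best$water_pref &&
               cand$coef_total < best$coef_total))))
          best <<- cand
      }
    })
    if (!is.null(best) || visited > budget) break
  }

  if (is.null(best)) return(result("unbalanceable"))

  new_p <- p
  new_p$stoichiometry <- as.integer(sides * best$mags)
  delta <- list()
  for (i in seq_len(nrow(p)))
    if (new_p$stoichiometry[i] != p$stoichiometry[i])
      delta[[length(delta) + 1L]] <- data.frame(
        chemical_id = p$chemical_id[i], old_stoich = p$stoichiometry[i],
        new_stoich = new_p$stoichiometry[i], stringsAsFactors = FALSE)
  for (j in seq_along(addable)) {
    if (best$adds[j] == 0) next
    new_p <- rbind(new_p, data.frame(
      chemical_id = addable[[j]]$id,
      stoichiometry = as.integer(best$adds[j]),
      role = "cofactor", stringsAsFactors = FALSE))
    delta[[length(delta) + 1L]] <- data.frame(
      chemical_id = addable[[j]]$id, old_stoich = 0L,
      new_stoich = as.integer(best$adds[j]), stringsAsFactors = FALSE)
  }
  result("rebalanced", new_p,
         if (length(delta) == 0) empty_delta() else do.call(rbind, delta))
}

empty_delta <- function() {
  data.frame(chemical_id = character(), old_stoich = integer(),
             new_stoich = integer(), stringsAsFactors = FALSE)
}

#' @export
print.kg_balance_result <- function(x, ...) {
  cat(sprintf("<kg_balance_result> %s; %d change(s)\n", x$status,
              nrow(x$delta)))
  invisible(x)
}

#' Balance every reaction in a graph
#'
#' Runs [balance_reaction()] over all reactions, rewrites corrected
#' stoichiometries onto the reaction-chemical edges (adding edges for
#' introduced species, which are matched to graph chemicals by formula and
#' charge), and stores the tri-state `balance` flag on each reaction node.
#'
#' @param graph A `kgraph` (modified in place).
#' @param config See [kg_config()].
#' @return Data frame with one row per reaction: `reaction_id`, `status`,
#'   `n_changes`, invisibly.
#' @export
balance_graph <- function(graph, config = kg_config()) {
  addable <- config$balance$addable_species %||% default_addable_species()
  # Repoint addable species onto the graph chemicals carrying the same
  # composition (formula + charge); species without a graph node cannot be
  # added and are dropped from the addable set.
  addable_key <- function(formula, charge)
    paste(formula, charge, sep = "\r")
  want <- vapply(addable, function(s) addable_key(s$formula, s$charge),
                 character(1))
  species_node <- rep(NA_character_, length(addable))
  for (id in graph_nodes(graph, "Chemical")) {
    chem <- get_node(graph, "Chemical", id)
    if (is.null(chem$formula) || is.null(chem$charge)) next
    k <- addable_key(chem$formula, chem$charge)
    hit <- which(want == k & is.na(species_node))
    if (length(hit) > 0) species_node[hit[1]] <- id
  }
  addable <- lapply(which(!is.na(species_node)), function(j) {
    s <- addable[[j]]
    s$id <- species_node[j]
    s
  })
  config$balance$addable_species <- addable

  chemicals <- graph$nodes$Chemical
  rows <- list()
  for (rid in graph_nodes(graph, "Reaction")) {
    rxn <- get_node(graph, "Reaction", rid)
    res <- balance_reaction(rxn, chemicals, config)
    status <- res$status
    if (status == "rebalanced") {
      rxn$participants <- res$participants
      rxn$balance <- TRUE
      graph$nodes$Reaction[[rid]] <- rxn
      rewrite_reaction_edges(graph, rid, res$participants)
    } else {
      rxn$balance <- switch(status, already_balanced = TRUE,
                            unbalanceable = FALSE, NA)
      graph$nodes$Reaction[[rid]] <- rxn
    }
    rows[[length(rows) + 1L]] <- data.frame(
      reaction_id = rid, status = status, n_changes = nrow(res$delta),
      stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, rows) %||%
              data.frame(reaction_id = character(), status = character(),
                         n_changes = integer(), stringsAsFactors = FALSE))
}

# Replace a reaction's has_reactant/has_cofactor edges with the given
# participant set, preserving each chemical's previous role where known.
rewrite_reaction_edges <- function(graph, reaction_id, participants) {
  rels <- graph$rels
  old_role <- character()
  keep <- vapply(rels, function(r) {
    !(r$from_id == reaction_id &&
        r$type %in% c("has_reactant", "has_cofactor"))
  }, logical(1))
  for (r in rels[!keep]) old_role[r$to_id] <-
    if (r$type == "has_cofactor") "cofactor" else "reactant"
  rels <- rels[keep]
  for (i in seq_len(nrow(participants))) {
    cid <- participants$chemical_id[i]
    role <- unname(old_role[cid])
    if (is.na(role) || !nzchar(role)) role <- participants$role[i]
    type <- if (identical(role, "cofactor")) "has_cofactor" else
      "has_reactant"
    rels[[length(rels) + 1L]] <- relationship(
      "Reaction", reaction_id, type, "Chemical", cid,
      properties = list(stoichiometry =
                          as.integer(participants$stoichiometry[i])))
  }
  set_relationships(graph, rels)
  # Participant roles follow the edge types.
  rxn <- get_node(graph, "Reaction", reaction_id)
  for (i in seq_len(nrow(rxn$participants))) {
    cid <- rxn$participants$chemical_id[i]
    if (!is.na(old_role[cid] %||% NA_character_) &&
        nzchar(old_role[cid] %||% ""))
      rxn$participants$role[i] <- unname(old_role[cid])
  }
  graph$nodes$Reaction[[reaction_id]] <- rxn
  invisible(graph)
}
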