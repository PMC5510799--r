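# Cross-source entity merging. Two records of the same label represent the
# same entity when they share at least one (namespace, accession)
# cross-reference pair; merging is transitive, computed as connected
# components over shared xrefs with a union-find structure. Property
# conflicts between sources are resolved by a configurable source
# precedence (by default ChEBI wins over MNXref for chemicals, MNXref over
# KEGG for reactions) and every losing value is logged so provenance is
# auditable.

uf_new <- function(n) seq_len(n)

#' Merge same-label entities that share cross-references
#'
#' Entities merge iff they share at least one (namespace, accession) pair;
#' merging is transitive. The merged entity's xrefs are the union of its
#' members'; scalar conflicts are resolved by source precedence with the
#' losing value logged; the canonical key is the highest-precedence
#' member's key. After merging, no two output entities share any xref
#' value, and re-running the merge on its own output is the identity.
#'
#' @param entities List of same-label entity records with normalised
#'   xrefs.
#' @param precedence Character vector of source names, highest precedence
#'   first (e.g. `c("chebi", "mnxref")`); unlisted sources rank below all
#'   listed ones, in input order.
#' @param label Node label of the entities (defaults to the label of the
#'   first entity).
#' @return List with `entities` (merged list) and `report` (a
#'   `kg_merge_report`: `merge_map` named character vector original key ->
#'   canonical key, and `conflicts` data frame with columns `key`,
#'   `property`, `kept_value`, `dropped_value`, `winning_source`).
#' @export
merge_entities <- function(entities, precedence = c("chebi", "mnxref"),
                           label = NULL) {
  if (length(entities) == 0)
    return(list(entities = entities, report = empty_merge_report()))
  if (is.null(label)) label <- entity_label(entities[[1]])
  keyf <- KEY_FIELDS[[label]]

  n <- length(entities)
  uf <- uf_new(n)
  find <- function(i) {
    root <- i
    while (uf[root] != root) root <- uf[root]
    while (uf[i] != root) { nxt <- uf[i]; uf[i] <- root; i <- nxt }
    uf <<- uf
    root
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) uf[min(ri, rj)] <- uf[max(ri, rj)] <- min(ri, rj)
    uf <<- uf
  }

  pair_owner <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    xr <- entities[[i]]$xrefs
    for (ns in names(xr)) {
      k <- paste(ns, xr[[ns]], sep = "\r")
      j <- pair_owner[[k]]
      if (is.null(j)) pair_owner[[k]] <- i else union_(i, j)
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)

  rank_of <- function(ent, idx) {
    src <- ent$source %||% ""
    r <- match(src, precedence)
    if (is.na(r)) r <- length(precedence) + 1L
    c(r, idx)
  }

  conflicts <- list()
  merged <- list()
  merge_map <- character()
  for (members in comp) {
    ranks <- t(vapply(members, function(i) rank_of(entities[[i]], i),
                      numeric(2)))
    ord <- members[order(ranks[, 1], ranks[, 2])]
    base <- entities[[ord[1]]]
    canonical <- base[[keyf]]
    for (i in ord[-1]) {
      other <- entities[[i]]
      merge_map[other[[keyf]]] <- canonical
      for (f in setdiff(names(other), c("xrefs", "names", keyf))) {
        ov <- other[[f]]; bv <- base[[f]]
        if (f == "participants") {
          if (is.data.frame(bv) && nrow(bv) == 0 && is.data.frame(ov) &&
              nrow(ov) > 0) base[[f]] <- ov
          next
        }
        if (is.null(ov) || (length(ov) == 1 && is.na(ov))) next
        if (is.null(bv) || (length(bv) == 1 && is.na(bv))) {
          base[[f]] <- ov
        } else if (f %in% c("ec", "ec_code")) {
          base[[f]] <- union(bv, ov)
        } else if (!identical(unname(bv), unname(ov)) && f != "source" &&
                   f != "participants") {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            key = canonical, property = f,
            kept_value = as.character(bv)[1],
            dropped_value = as.character(ov)[1],
            winning_source = base$source %||% "", stringsAsFactors = FALSE)
        }
      }
      base$names <- setdiff(union(base$names,
                                  c(other$names, other$name %||% character())),
                            base$name %||% character())
      for (ns in names(other$xrefs)) {
        if (!(ns %in% names(base$xrefs))) {
          base$xrefs[ns] <- other$xrefs[[ns]]
        } else if (!identical(unname(base$xrefs[[ns]]), other$xrefs[[ns]])) {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            key = canonical, property = paste0("xref:", ns),
            kept_value = unname(base$xrefs[[ns]]),
            dropped_value = other$xrefs[[ns]],
            winning_source = base$source %||% "", stringsAsFactors = FALSE)
        }
      }
    }
    merge_map[canonical] <- canonical
    merged[[length(merged) + 1L]] <- base
  }

  # Preserve input order: components ordered by first member.
  first_member <- vapply(comp, min, integer(1))
  merged <- merged[order(first_member)]

  report <- structure(
    list(merge_map = merge_map,
         conflicts = if (length(conflicts) == 0) empty_conflicts()
                     else do.call(rbind, conflicts)),
    class = "kg_merge_report")
  list(entities = merged, report = report)
}

empty_conflicts <- function() {
  data.frame(key = character(), property = character(),
             kept_value = character(), dropped_value = character(),
             winning_source = character(), stringsAsFactors = FALSE)
}

empty_merge_report <- function() {
  structure(list(merge_map = character(), conflicts = empty_conflicts()),
            class = "kg_merge_report")
}

#' Write a merge report as CSV
#'
#' @param report A `kg_merge_report` from [merge_entities()] or
#'   [build_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(report, path) {
  mm <- data.frame(original_key = names(report$merge_map),
                   canonical_key = unname(report$merge_map),
                   stringsAsFactors = FALSE)
  utils::write.csv(mm, path, row.names = FALSE)
  conflict_path <- sub("(\\.[^.]+)?$", "_conflicts\\1", path)
  utils::write.csv(report$conflicts, conflict_path, row.names = FALSE)
  invisible(path)
}

#' @export
print.kg_merge_report <- function(x, ...) {
  n_merged <- sum(names(x$merge_map) != x$merge_map)
  cat(sprintf("<kg_merge_report> %d key(s) remapped, %d conflict(s)\n",
              n_merged, nrow(x$conflicts)))
  invisible(x)
}
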