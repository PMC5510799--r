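# Bulk serialization. The CSV dialect follows the batch-import header
# convention of property-graph engines (`:ID`, `:LABEL`, `:START_ID`,
# `:END_ID`, `:TYPE`, `:string[]` array columns with ';' delimiters), so
# the output of write_bulk_csv can seed a real server although none is
# required. Exports are byte-stable for a given graph: rows are sorted by
# key and all files are UTF-8 with LF line endings.

# Fixed property columns per label (beyond the key, xrefs and :LABEL).
NODE_BASE_COLUMNS <- list(
  Organism = c("name", "names:string[]"),
  Enzyme = c("entry", "name", "names:string[]", "ec_code:string[]"),
  Reaction = c("name", "ec:string[]", "balance:boolean", "source"),
  Chemical = c("name", "names:string[]", "formula", "charge:int",
               "monoisotopic_mass:double", "inchi", "smiles", "source")
)

NODE_FILES <- c(Organism = "organisms.csv", Enzyme = "enzymes.csv",
                Reaction = "reactions.csv", Chemical = "chemicals.csv")

fmt_num <- function(x) {
  if (is.null(x) || is.na(x)) return("")
  sprintf("%.12g", x)
}

fmt_bool <- function(x) {
  if (is.null(x) || is.na(x)) return("")
  if (isTRUE(x)) "true" else "false"
}

fmt_chr <- function(x) if (is.null(x) || is.na(x)) "" else as.character(x)

fmt_arr <- function(x) paste(x, collapse = ";")

node_cell <- function(entity, col) {
  base <- sub(":(string\\[\\]|boolean|int|double)$", "", col)
  val <- entity[[base]]
  if (endsWith(col, ":string[]")) return(fmt_arr(val))
  if (endsWith(col, ":boolean")) return(fmt_bool(val))
  if (endsWith(col, ":int")) return(fmt_chr(val))
  if (endsWith(col, ":double")) return(fmt_num(val))
  fmt_chr(val)
}

#' Write a graph as bulk-import CSV
#'
#' One nodes file per label (header `<key>:ID,<prop>,...,:LABEL`; array
#' cells ';'-joined; chemical and reaction cross-references flattened into
#' one column per namespace) and one relationships file per relationship
#' type present (header `:START_ID,:END_ID,:TYPE,<prop>...`). A
#' `manifest.json` lists every file with its row count.
#'
#' @param graph A `kgraph`.
#' @param out_dir Output directory (created if needed).
#' @return Manifest list (`files`: data frame with `file`, `kind`,
#'   `label_or_type`, `rows`), invisibly.
#' @export
write_bulk_csv <- function(graph, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    kg_io_error(sprintf("cannot write to directory: %s", out_dir))

  files <- list()
  for (label in NODE_LABELS) {
    keys <- sort(graph_nodes(graph, label))
    ents <- lapply(keys, function(k) get_node(graph, label, k))
    ns_cols <- character()
    if (label %in% c("Chemical", "Reaction"))
      ns_cols <- sort(unique(unlist(lapply(ents, function(e)
        names(e$xrefs)))))
    header <- c(paste0(KEY_FIELDS[[label]], ":ID"),
                NODE_BASE_COLUMNS[[label]], ns_cols, ":LABEL")
    rows <- vapply(ents, function(e) {
      cells <- c(e[[KEY_FIELDS[[label]]]],
                 vapply(NODE_BASE_COLUMNS[[label]], node_cell,
                        character(1), entity = e),
                 vapply(ns_cols, function(ns)
                   fmt_chr(unname(e$xrefs[ns])), character(1)),
                 label)
      paste(vapply(cells, csv_quote, character(1)), collapse = ",")
    }, character(1))
    path <- file.path(out_dir, NODE_FILES[[label]])
    write_lf(c(paste(vapply(header, csv_quote, character(1)),
                     collapse = ","), rows), path)
    files[[length(files) + 1L]] <- data.frame(
      file = NODE_FILES[[label]], kind = "nodes", label_or_type = label,
      rows = length(rows), stringsAsFactors = FALSE)
  }

  rels <- graph_relationships(graph)
  for (type in sort(unique(rels$type))) {
    sub <- rels[rels$type == type, , drop = FALSE]
    sub <- sub[order(sub$from_id, sub$to_id, sub$source,
                     sub$stoichiometry), , drop = FALSE]
    props <- c(if (!all(is.na(sub$stoichiometry))) "stoichiometry:int",
               if (!all(is.na(sub$source))) "source")
    header <- c(":START_ID", ":END_ID", ":TYPE", props)
    rows <- vapply(seq_len(nrow(sub)), function(i) {
      cells <- c(sub$from_id[i], sub$to_id[i], type)
      if ("stoichiometry:int" %in% props)
        cells <- c(cells, fmt_chr(sub$stoichiometry[i]))
      if ("source" %in% props) cells <- c(cells, fmt_chr(sub$source[i]))
      paste(vapply(cells, csv_quote, character(1)), collapse = ",")
    }, character(1))
    fname <- sprintf("relationships_%s.csv", type)
    write_lf(c(paste(vapply(header, csv_quote, character(1)),
                     collapse = ","), rows),
             file.path(out_dir, fname))
    files[[length(files) + 1L]] <- data.frame(
      file = fname, kind = "relationships", label_or_type = type,
      rows = nrow(sub), stringsAsFactors = FALSE)
  }

  manifest <- list(files = do.call(rbind, files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# RFC 4180 quoting: quote when the cell contains a comma, quote or
# newline; embedded quotes double.
csv_quote <- function(x) {
  if (grepl('[",\n\r]', x))
    paste0('"', gsub('"', '""', x), '"')
  else x
}

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# RFC 4180 line splitter (handles quoted cells with embedded commas,
# quotes and the quote-doubling escape).
csv_split <- function(line) {
  out <- character()
  cell <- character(0)
  chars <- strsplit(line, "")[[1]]
  in_q <- FALSE
  buf <- ""
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_q) {
      if (ch == '"') {
        if (i < n && chars[i + 1] == '"') { buf <- paste0(buf, '"'); i <- i + 1 }
        else in_q <- FALSE
      } else buf <- paste0(buf, ch)
    } else {
      if (ch == '"') in_q <- TRUE
      else if (ch == ",") { out <- c(out, buf); buf <- "" }
      else buf <- paste0(buf, ch)
    }
    i <- i + 1
  }
  c(out, buf)
}

read_csv_table <- function(path) {
  lines <- read_source_lines(path)
  if (length(lines) == 0) kg_io_error(sprintf("empty csv: %s", path))
  header <- csv_split(lines[1])
  rows <- lapply(lines[-1], csv_split)
  list(header = header, rows = rows)
}

#' Read a bulk-CSV directory back into a graph
#'
#' Inverse of [write_bulk_csv()]: reconstructs a graph isomorphic to the
#' exported one (same nodes, properties and typed relationships with
#' properties). Relationship endpoints are resolved through the type's
#' label signature; an endpoint that resolves to no existing node is a
#' referential-integrity error. Unknown node-file columns are preserved as
#' string properties with a warning.
#'
#' @param dir Directory produced by [write_bulk_csv()].
#' @return A `kgraph`.
#' @export
read_bulk_csv <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    kg_io_error(sprintf("manifest.json not found in %s", dir))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  files <- manifest$files
  graph <- kgraph()

  node_files <- files[files$kind == "nodes", , drop = FALSE]
  rel_files <- files[files$kind == "relationships", , drop = FALSE]
  for (f in c(node_files$file, rel_files$file))
    if (!file.exists(file.path(dir, f)))
      kg_io_error(sprintf("file listed in manifest is missing: %s", f))

  for (i in seq_len(nrow(node_files))) {
    tab <- read_csv_table(file.path(dir, node_files$file[i]))
    label <- node_files$label_or_type[i]
    parse_node_rows(graph, label, tab)
  }
  for (i in seq_len(nrow(rel_files))) {
    tab <- read_csv_table(file.path(dir, rel_files$file[i]))
    parse_rel_rows(graph, tab)
  }

  # Participant lists and organism parent pointers are carried by the
  # relationship files; rebuild the node-side mirrors from the edges.
  rels <- graph_relationships(graph)
  pe <- rels[rels$type %in% c("has_reactant", "has_cofactor"), ,
             drop = FALSE]
  for (rid in graph_nodes(graph, "Reaction")) {
    sub <- pe[pe$from_id == rid, , drop = FALSE]
    rxn <- get_node(graph, "Reaction", rid)
    rxn$participants <- data.frame(
      chemical_id = sub$to_id,
      stoichiometry = as.integer(sub$stoichiometry),
      role = ifelse(sub$type == "has_cofactor", "cofactor", "reactant"),
      stringsAsFactors = FALSE)
    graph$nodes$Reaction[[rid]] <- rxn
  }
  isa <- rels[rels$type == "is_a" & rels$from_label == "Organism", ,
              drop = FALSE]
  for (i in seq_len(nrow(isa))) {
    org <- get_node(graph, "Organism", isa$from_id[i])
    org$parent_taxonomy <- isa$to_id[i]
    graph$nodes$Organism[[isa$from_id[i]]] <- org
  }
  graph
}

parse_node_rows <- function(graph, label, tab) {
  header <- tab$header
  key_col <- paste0(KEY_FIELDS[[label]], ":ID")
  if (!(key_col %in% header))
    kg_io_error(sprintf("%s file lacks key column %s", label, key_col))
  known <- c(key_col, NODE_BASE_COLUMNS[[label]], ":LABEL")
  ns_set <- if (label == "Chemical") CHEMICAL_NAMESPACES
            else if (label == "Reaction") REACTION_NAMESPACES
            else character()
  for (row in tab$rows) {
    row <- c(row, rep("", max(0, length(header) - length(row))))
    cell <- stats::setNames(row[seq_along(header)], header)
    ent <- list()
    ent[[KEY_FIELDS[[label]]]] <- cell[[key_col]]
    xrefs <- character()
    for (col in header) {
      if (col %in% c(key_col, ":LABEL")) next
      v <- cell[[col]]
      if (!nzchar(v)) next
      base <- sub(":(string\\[\\]|boolean|int|double)$", "", col)
      if (col %in% known) {
        if (endsWith(col, ":string[]"))
          ent[[base]] <- strsplit(v, ";", fixed = TRUE)[[1]]
        else if (endsWith(col, ":boolean")) ent[[base]] <- v == "true"
        else if (endsWith(col, ":int")) ent[[base]] <- as.integer(v)
        else if (endsWith(col, ":double")) ent[[base]] <- as.numeric(v)
        else ent[[base]] <- v
      } else if (col %in% ns_set) {
        xrefs[col] <- v
      } else {
        warning(sprintf("%s file: unknown column '%s' kept as string",
                        label, col), call. = FALSE)
        ent[[base]] <- v
      }
    }
    if (length(xrefs) > 0) ent$xrefs <- xrefs
    known_fields <- switch(label,
      Chemical = names(formals(chemical_entity)),
      Reaction = names(formals(reaction_entity)),
      Enzyme = names(formals(enzyme_entity)),
      Organism = names(formals(organism_entity)))
    extra <- ent[setdiff(names(ent), known_fields)]
    ent <- ent[intersect(names(ent), known_fields)]
    key <- upsert_node(graph, label, ent)
    if (length(extra) > 0) {
      node <- get_node(graph, label, key)
      for (nm in names(extra)) node[[nm]] <- extra[[nm]]
      graph$nodes[[label]][[key]] <- node
    }
  }
  invisible(graph)
}

parse_rel_rows <- function(graph, tab) {
  header <- tab$header
  for (row in tab$rows) {
    row <- c(row, rep("", max(0, length(header) - length(row))))
    cell <- stats::setNames(row[seq_along(header)], header)
    type <- cell[[":TYPE"]]
    sig <- REL_SIGNATURES[[type]]
    if (is.null(sig))
      kg_schema_error(sprintf("unknown relationship type '%s'", type))
    hit <- NULL
    for (s in sig) {
      if (!is.null(get_node(graph, s[1], cell[[":START_ID"]])) &&
          !is.null(get_node(graph, s[2], cell[[":END_ID"]]))) {
        hit <- s
        break
      }
    }
    if (is.null(hit))
      kg_validation_error(sprintf(
        "referential integrity: %s edge %s->%s has no resolvable endpoints",
        type, cell[[":START_ID"]], cell[[":END_ID"]]))
    props <- list()
    if ("stoichiometry:int" %in% header &&
        nzchar(cell[["stoichiometry:int"]]))
      props$stoichiometry <- as.integer(cell[["stoichiometry:int"]])
    if ("source" %in% header && nzchar(cell[["source"]]))
      props$source <- cell[["source"]]
    add_relationship(graph, relationship(
      hit[1], cell[[":START_ID"]], type, hit[2], cell[[":END_ID"]], props))
  }
  invisible(graph)
}

#' Write query result rows
#'
#' CSV output is RFC 4180 with a header row; JSON output is an array of
#' objects keyed by the row field names (an empty row set serialises as
#' `[]`).
#'
#' @param rows Data frame of homogeneous rows.
#' @param format `"csv"` or `"json"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, format, path) {
  if (!is.data.frame(rows)) kg_validation_error("rows must be a data frame")
  if (!format %in% c("csv", "json"))
    kg_validation_error(sprintf("unknown format '%s'", format))
  if (format == "csv") {
    cells <- function(v) vapply(v, csv_quote, character(1))
    lines <- c(paste(cells(names(rows)), collapse = ","),
               if (nrow(rows) > 0)
                 vapply(seq_len(nrow(rows)), function(i)
                   paste(cells(vapply(rows[i, , drop = FALSE],
                                      function(x)
                                        if (is.na(x)) "" else
                                          if (is.numeric(x)) fmt_num(x)
                                          else as.character(x),
                                      character(1))),
                         collapse = ","), character(1)))
    write_lf(lines, path)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a CSV written by write_results
#'
#' @param path CSV file.
#' @return Data frame of character columns.
#' @export
read_results_csv <- function(path) {
  tab <- read_csv_table(path)
  rows <- tab$rows
  m <- if (length(rows) == 0)
    matrix(character(), ncol = length(tab$header))
  else do.call(rbind, lapply(rows, function(r)
    c(r, rep("", max(0, length(tab$header) - length(r))))[
      seq_along(tab$header)]))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- tab$header
  df
}
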