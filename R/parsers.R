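# Flat-file parsers for the miniature source dialects. Real-world release
# layouts of the upstream databases vary; the dialects accepted here are
# frozen and documented per function so that graphs can be built and tested
# without any download. All readers accept LF and CRLF line endings and
# skip comment ('#') and trailing blank lines.

read_source_lines <- function(path) {
  if (!file.exists(path)) kg_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  while (length(lines) > 0 && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  lines
}

strip_comments <- function(lines) {
  keep <- !startsWith(lines, "#") & nzchar(lines)
  structure(lines[keep], line_numbers = which(keep))
}

#' Parse an NCBI-style taxonomy dump
#'
#' `nodes_file` uses the dmp dialect: fields separated by `"\t|\t"`, lines
#' terminated by `"\t|"`, columns (tax_id, parent_tax_id, rank, ...).
#' `names_file` has columns (tax_id, name_txt, unique_name, name_class).
#' The `"scientific name"` entry becomes the organism's `name`; all other
#' name classes are collected into `names`. Every non-root node yields an
#' `is_a` edge child to parent; the root (tax_id equal to its parent) gets
#' no self-edge.
#'
#' @param nodes_file,names_file Paths to the two dump files.
#' @return List with `organisms` (list of [organism_entity()]) and
#'   `relationships` (list of is_a [relationship()] records).
#' @export
parse_taxonomy_dump <- function(nodes_file, names_file) {
  split_dmp <- function(line) {
    line <- sub("\t\\|$", "", line)
    strsplit(line, "\t|\t", fixed = TRUE)[[1]]
  }
  nl <- strip_comments(read_source_lines(nodes_file))
  nums <- attr(nl, "line_numbers")
  tax <- list()
  for (i in seq_along(nl)) {
    f <- split_dmp(nl[i])
    if (length(f) < 3)
      kg_parse_error(sprintf("nodes dump: expected >= 3 fields, got %d",
                             length(f)), line = nums[i])
    tax[[f[1]]] <- list(parent = f[2], rank = f[3])
  }

  ml <- strip_comments(read_source_lines(names_file))
  mnums <- attr(ml, "line_numbers")
  sci <- list(); syn <- list()
  for (i in seq_along(ml)) {
    f <- split_dmp(ml[i])
    if (length(f) < 4)
      kg_parse_error(sprintf("names dump: expected 4 fields, got %d",
                             length(f)), line = mnums[i])
    id <- f[1]
    if (is.null(tax[[id]])) {
      warning(sprintf("names dump: tax_id '%s' absent from nodes dump, skipped",
                      id), call. = FALSE)
      next
    }
    if (f[4] == "scientific name") sci[[id]] <- f[2]
    else syn[[id]] <- c(syn[[id]], f[2])
  }

  organisms <- list(); rels <- list()
  for (id in names(tax)) {
    parent <- tax[[id]]$parent
    is_root <- identical(parent, id)
    organisms[[length(organisms) + 1L]] <- organism_entity(
      taxonomy = id, name = sci[[id]], names = syn[[id]] %||% character(),
      parent_taxonomy = if (is_root) NULL else parent)
    if (!is_root)
      rels[[length(rels) + 1L]] <- relationship(
        "Organism", id, "is_a", "Organism", parent)
  }
  list(organisms = organisms, relationships = rels)
}

split_tsv <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

field_or_null <- function(fields, i) {
  if (length(fields) < i) return(NULL)
  v <- trimws(fields[i])
  if (!nzchar(v) || toupper(v) %in% c("NA", "N/A")) NULL else v
}

#' Parse an MNXref-style chemical property table
#'
#' TSV with `#`-prefixed comment header and columns (id, name, formula,
#' charge, mass, inchi, smiles, xref); `xref` holds one
#' `"namespace:accession"` whose namespace token is normalised through
#' [normalize_namespace_key()]. Empty cells become absent fields; a
#' non-integer charge is dropped with a warning; a duplicate id is a parse
#' error.
#'
#' @param chem_prop_file Path to the table.
#' @return List of [chemical_entity()] records.
#' @export
parse_mnxref_chemicals <- function(chem_prop_file) {
  lines <- strip_comments(read_source_lines(chem_prop_file))
  out <- list()
  seen <- character()
  for (i in seq_along(lines)) {
    f <- split_tsv(lines[i])
    id <- field_or_null(f, 1)
    if (is.null(id))
      kg_parse_error("chem_prop: missing id",
                     line = attr(lines, "line_numbers")[i])
    if (id %in% seen)
      kg_parse_error(sprintf("chem_prop: duplicate id '%s'", id))
    seen <- c(seen, id)
    # distinguish an empty charge cell (silently absent) from a degenerate
    # non-integer one (dropped with a warning)
    charge_raw <- if (length(f) >= 4) trimws(f[4]) else ""
    charge <- NULL
    if (nzchar(charge_raw)) {
      ch <- suppressWarnings(as.integer(charge_raw))
      if (is.na(ch) || suppressWarnings(as.numeric(charge_raw)) != ch) {
        warning(sprintf("chem_prop '%s': non-integer charge '%s' dropped",
                        id, charge_raw), call. = FALSE)
      } else charge <- ch
    }
    mass <- field_or_null(f, 5)
    if (!is.null(mass)) mass <- as.numeric(mass)
    xrefs <- c(mnx = id)
    xr <- field_or_null(f, 8)
    if (!is.null(xr)) {
      parts <- strsplit(xr, ":", fixed = TRUE)[[1]]
      if (length(parts) >= 2) {
        ns <- normalize_namespace_key(parts[1], "Chemical")
        acc <- paste(parts[-1], collapse = ":")
        if (ns == "chebi" && !startsWith(acc, "CHEBI:"))
          acc <- paste0("CHEBI:", acc)
        xrefs[ns] <- acc
      }
    }
    out[[length(out) + 1L]] <- chemical_entity(
      id = id, name = field_or_null(f, 2), formula = field_or_null(f, 3),
      charge = charge, monoisotopic_mass = mass,
      inchi = field_or_null(f, 6), smiles = field_or_null(f, 7),
      xrefs = xrefs, source = "mnxref")
  }
  out
}

# Equation grammar: `coef chem (+ coef chem)* = coef chem (+ coef chem)*`,
# positive integer coefficients, default 1.
parse_equation <- function(equation, reaction_id) {
  sides <- strsplit(equation, "=", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    kg_parse_error(sprintf("reaction '%s': unparseable equation '%s'",
                           reaction_id, equation))
  term_list <- function(side, sgn) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    out <- list()
    for (t in terms) {
      bits <- strsplit(t, "[ \t]+")[[1]]
      bits <- bits[nzchar(bits)]
      if (length(bits) == 1) {
        coef <- 1L; id <- bits[1]
      } else if (length(bits) == 2) {
        coef <- suppressWarnings(as.integer(bits[1]))
        id <- bits[2]
        if (is.na(coef) || coef <= 0 ||
            as.numeric(bits[1]) != coef)
          kg_parse_error(sprintf(
            "reaction '%s': bad coefficient '%s'", reaction_id, bits[1]))
      } else {
        kg_parse_error(sprintf("reaction '%s': unparseable term '%s'",
                               reaction_id, t))
      }
      out[[length(out) + 1L]] <- list(id = id, stoich = sgn * coef)
    }
    out
  }
  terms <- c(term_list(sides[1], -1L), term_list(sides[2], +1L))
  ids <- vapply(terms, `[[`, character(1), "id")
  st <- vapply(terms, `[[`, integer(1), "stoich")
  net <- tapply(st, ids, sum)
  if (any(net == 0))
    warning(sprintf("reaction '%s': net-zero participant(s) dropped: %s",
                    reaction_id,
                    paste(names(net)[net == 0], collapse = ", ")),
            call. = FALSE)
  net <- net[net != 0]
  if (length(net) == 0) return(empty_participants())
  data.frame(chemical_id = names(net)[order(match(names(net), ids))],
             stoichiometry = as.integer(net[order(match(names(net), ids))]),
             role = "reactant", stringsAsFactors = FALSE)
}

#' Parse an MNXref-style reaction property table
#'
#' TSV columns (id, equation, ec, balance, xref). Left-hand-side
#' participants get negative stoichiometry, right-hand-side positive; all
#' participants start with role `"reactant"` (cofactor annotation happens
#' at graph build). The balance column maps to the tri-state flag
#' (`true`/`false`/empty).
#'
#' @param reac_prop_file Path to the table.
#' @return List of [reaction_entity()] records.
#' @export
parse_mnxref_reactions <- function(reac_prop_file) {
  lines <- strip_comments(read_source_lines(reac_prop_file))
  out <- list()
  for (i in seq_along(lines)) {
    f <- split_tsv(lines[i])
    id <- field_or_null(f, 1)
    if (is.null(id))
      kg_parse_error("reac_prop: missing id",
                     line = attr(lines, "line_numbers")[i])
    eq <- field_or_null(f, 2)
    participants <- if (is.null(eq)) empty_participants()
                    else parse_equation(eq, id)
    ec <- field_or_null(f, 3)
    ec <- if (is.null(ec)) character() else
      trimws(strsplit(ec, ";", fixed = TRUE)[[1]])
    bal <- field_or_null(f, 4)
    bal <- if (is.null(bal)) NA else identical(tolower(bal), "true")
    xrefs <- c(mnx = id)
    xr <- field_or_null(f, 5)
    if (!is.null(xr)) {
      parts <- strsplit(xr, ":", fixed = TRUE)[[1]]
      if (length(parts) >= 2) {
        ns <- normalize_namespace_key(parts[1], "Reaction")
        xrefs[ns] <- paste(parts[-1], collapse = ":")
      }
    }
    out[[length(out) + 1L]] <- reaction_entity(
      id = id, ec = ec, balance = bal, xrefs = xrefs, source = "mnxref",
      participants = participants)
  }
  out
}

#' Parse a simplified ChEBI-style ontology export
#'
#' Four TSV tables: `compounds_file` (chebi_id, name); `relations_file`
#' (type, child_chebi_id, parent_chebi_id) with types among the nine
#' chemical-chemical relation names; `data_file` (chebi_id, key, value)
#' with keys `FORMULA`, `CHARGE`, `MONOISOTOPIC MASS`; `names_file`
#' (chebi_id, synonym). Relationship direction is child to parent.
#' Relations of unknown type or referencing unknown ids are skipped with a
#' warning. Compounds without formula data remain valid class nodes.
#'
#' @param compounds_file,relations_file,data_file,names_file Paths.
#' @return List with `chemicals` (list of [chemical_entity()]) and
#'   `relationships` (list of chemical-chemical [relationship()] records).
#' @export
parse_chebi_ontology <- function(compounds_file, relations_file, data_file,
                                 names_file) {
  comp <- strip_comments(read_source_lines(compounds_file))
  props <- list()   # id -> list(formula, charge, mass)
  syns <- list()
  name_of <- list()
  order_ids <- character()
  for (i in seq_along(comp)) {
    f <- split_tsv(comp[i])
    id <- field_or_null(f, 1)
    if (is.null(id))
      kg_parse_error("chebi compounds: missing id",
                     line = attr(comp, "line_numbers")[i])
    name_of[[id]] <- field_or_null(f, 2)
    order_ids <- c(order_ids, id)
  }

  dl <- strip_comments(read_source_lines(data_file))
  for (i in seq_along(dl)) {
    f <- split_tsv(dl[i])
    id <- field_or_null(f, 1); key <- field_or_null(f, 2)
    val <- field_or_null(f, 3)
    if (is.null(id) || is.null(key) || is.null(val)) next
    if (is.null(name_of[[id]])) {
      warning(sprintf("chebi data: unknown id '%s', skipped", id),
              call. = FALSE)
      next
    }
    p <- props[[id]] %||% list()
    if (key == "FORMULA") p$formula <- val
    else if (key == "CHARGE") p$charge <- suppressWarnings(as.integer(val))
    else if (key == "MONOISOTOPIC MASS") p$mass <- as.numeric(val)
    props[[id]] <- p
  }

  nl <- strip_comments(read_source_lines(names_file))
  for (i in seq_along(nl)) {
    f <- split_tsv(nl[i])
    id <- field_or_null(f, 1); syn <- field_or_null(f, 2)
    if (is.null(id) || is.null(syn)) next
    if (is.null(name_of[[id]])) next
    syns[[id]] <- c(syns[[id]], syn)
  }

  chemicals <- lapply(order_ids, function(id) {
    p <- props[[id]] %||% list()
    chemical_entity(id = id, name = name_of[[id]],
                    names = syns[[id]] %||% character(),
                    formula = p$formula, charge = p$charge,
                    monoisotopic_mass = p$mass,
                    xrefs = c(chebi = id), source = "chebi")
  })

  rl <- strip_comments(read_source_lines(relations_file))
  rels <- list()
  for (i in seq_along(rl)) {
    f <- split_tsv(rl[i])
    type <- field_or_null(f, 1)
    child <- field_or_null(f, 2); parent <- field_or_null(f, 3)
    if (is.null(type) || is.null(child) || is.null(parent))
      kg_parse_error("chebi relations: expected 3 fields",
                     line = attr(rl, "line_numbers")[i])
    if (!(type %in% CHEMICAL_RELATION_TYPES)) {
      warning(sprintf("chebi relations: unknown type '%s' skipped", type),
              call. = FALSE)
      next
    }
    if (is.null(name_of[[child]]) || is.null(name_of[[parent]])) {
      warning(sprintf("chebi relations: unknown id in %s(%s, %s), skipped",
                      type, child, parent), call. = FALSE)
      next
    }
    rels[[length(rels) + 1L]] <- relationship(
      "Chemical", child, type, "Chemical", parent)
  }
  list(chemicals = chemicals, relationships = rels)
}

#' Parse a UniProt-like protein table
#'
#' TSV with header row and columns (uniprot, entry, name, synonyms, ec,
#' taxonomy_id, reaction_xrefs); `synonyms` and `ec` are `;`-joined lists,
#' `reaction_xrefs` is a `;`-joined list of `"namespace:accession"`. Each
#' row yields an enzyme record and a deferred `expresses` link; reaction
#' cross-references are returned as deferred links to be resolved once all
#' reactions are loaded (carrying the enzyme/reaction link role of the
#' KEGG and Rhea sources). Rows sharing a UniProt accession collapse to
#' one enzyme: the first-loaded name is kept and later names become
#' synonyms.
#'
#' @param protein_file Path to the table.
#' @return List with `enzymes` (list of [enzyme_entity()]), `expresses`
#'   (data frame `taxonomy`, `uniprot`, `source`) and `reaction_links`
#'   (data frame `uniprot`, `namespace`, `accession`).
#' @export
parse_protein_table <- function(protein_file) {
  lines <- strip_comments(read_source_lines(protein_file))
  if (length(lines) == 0)
    return(list(enzymes = list(),
                expresses = data.frame(taxonomy = character(),
                                       uniprot = character(),
                                       source = character(),
                                       stringsAsFactors = FALSE),
                reaction_links = data.frame(uniprot = character(),
                                            namespace = character(),
                                            accession = character(),
                                            stringsAsFactors = FALSE)))
  header <- split_tsv(lines[1])
  need <- c("uniprot", "entry", "name", "synonyms", "ec", "taxonomy_id",
            "reaction_xrefs")
  if (!all(need %in% header))
    kg_parse_error(sprintf("protein table: missing column(s): %s",
                           paste(setdiff(need, header), collapse = ", ")))
  col <- function(f, nm) field_or_null(f, match(nm, header))
  enzymes <- list()
  expresses <- list()
  links <- list()
  for (i in seq_along(lines)[-1]) {
    f <- split_tsv(lines[i])
    up <- col(f, "uniprot")
    if (is.null(up))
      kg_parse_error("protein table: missing uniprot accession",
                     line = attr(lines, "line_numbers")[i])
    split_list <- function(x) if (is.null(x)) character() else
      trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    ent <- enzyme_entity(uniprot = up, entry = col(f, "entry"),
                         ec_code = split_list(col(f, "ec")),
                         name = col(f, "name"),
                         names = split_list(col(f, "synonyms")))
    if (is.null(enzymes[[up]])) enzymes[[up]] <- ent
    else enzymes[[up]] <- merge_records(enzymes[[up]], ent)
    taxon <- col(f, "taxonomy_id")
    if (!is.null(taxon))
      expresses[[length(expresses) + 1L]] <-
        data.frame(taxonomy = taxon, uniprot = up, source = "uniprot",
                   stringsAsFactors = FALSE)
    for (xr in split_list(col(f, "reaction_xrefs"))) {
      parts <- strsplit(xr, ":", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      ns <- normalize_namespace_key(parts[1], "Reaction")
      links[[length(links) + 1L]] <-
        data.frame(uniprot = up, namespace = ns,
                   accession = paste(parts[-1], collapse = ":"),
                   stringsAsFactors = FALSE)
    }
  }
  bindrows <- function(lst, proto) if (length(lst) == 0) proto else
    unique(do.call(rbind, lst))
  list(
    enzymes = unname(enzymes),
    expresses = bindrows(expresses,
                         data.frame(taxonomy = character(),
                                    uniprot = character(),
                                    source = character(),
                                    stringsAsFactors = FALSE)),
    reaction_links = bindrows(links,
                              data.frame(uniprot = character(),
                                         namespace = character(),
                                         accession = character(),
                                         stringsAsFactors = FALSE)))
}
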