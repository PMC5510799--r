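# Entity record constructors. Entities are plain lists tagged with an S3
# class; validation happens both here and at upsert time so records built by
# hand or parsed from files go through the same checks.

#' Valid identifiers.org namespace keys for chemical cross-references
#'
#' The namespace keys a Chemical node may carry as cross-reference
#' properties (the union of database identifiers a chemical record can be
#' annotated with).
#' @keywords internal
CHEMICAL_NAMESPACES <- c(
  "bigg.metabolite", "cas", "chebi", "chemidplus", "chemspider", "drugbank",
  "hmdb", "kegg.compound", "kegg.drug", "kegg.glycan", "knapsack",
  "lipidmaps", "metacyc", "mnx", "molbase", "pdb", "pubmed", "reactome",
  "resid", "seed.compound", "umbbd.compound", "unipathway", "wikipedia.en"
)

#' Valid identifiers.org namespace keys for reaction cross-references
#' @keywords internal
REACTION_NAMESPACES <- c(
  "bigg.reaction", "kegg.reaction", "metacyc", "mnx", "reactome", "rhea",
  "seed"
)

#' The four node labels of the knowledge graph
#' @keywords internal
NODE_LABELS <- c("Organism", "Enzyme", "Reaction", "Chemical")

# Property used as the node key, per label.
KEY_FIELDS <- c(Organism = "taxonomy", Enzyme = "uniprot",
                Reaction = "id", Chemical = "id")

#' Create a chemical entity record
#'
#' A chemical species or chemical class. Generic class nodes (for example
#' "fatty acid") typically carry neither a formula nor a mass; that is
#' allowed, and such nodes simply never match mass-filtered queries.
#'
#' @param id Unique key, e.g. `"CHEBI:15422"` or `"MNXM3"`.
#' @param name Preferred name.
#' @param names Character vector of synonyms.
#' @param formula Molecular formula string (e.g. `"C6H12O6"`), or `NULL`.
#' @param charge Integer charge (may be negative), or `NULL`.
#' @param monoisotopic_mass Monoisotopic mass in Da, or `NULL`.
#' @param inchi,smiles Structure line notations, or `NULL`.
#' @param xrefs Named character vector mapping identifiers.org namespace
#'   keys (see `CHEMICAL_NAMESPACES`) to accessions.
#' @param source Name of the originating database (e.g. `"chebi"`).
#' @return A list of class `"chemical_entity"`.
#' @export
chemical_entity <- function(id, name = NULL, names = character(),
                            formula = NULL, charge = NULL,
                            monoisotopic_mass = NULL, inchi = NULL,
                            smiles = NULL, xrefs = character(),
                            source = NULL) {
  formula <- sanitize_formula(formula, id)
  ent <- structure(
    list(id = as.character(id), name = name, names = as.character(names),
         formula = formula, charge = charge,
         monoisotopic_mass = monoisotopic_mass, inchi = inchi,
         smiles = smiles, xrefs = as_xrefs(xrefs), source = source),
    class = c("chemical_entity", "kg_entity"))
  validate_entity(ent, "Chemical")
  ent
}

# A generic/polymeric formula (R-groups, '*', 'n' repeats, parentheses)
# demotes the record to a class node: the formula is dropped with a warning
# so mass-based logic treats it as unknown. Malformed formulas are a hard
# validation error.
sanitize_formula <- function(formula, id) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  tryCatch({
    parse_formula(formula)
    formula
  },
  kg_generic_formula = function(e) {
    warning(sprintf("chemical '%s': generic formula '%s' dropped (class node)",
                    id, formula), call. = FALSE)
    NULL
  },
  kg_parse_error = function(e) {
    kg_validation_error(sprintf("chemical '%s': invalid formula '%s': %s",
                                id, formula, conditionMessage(e)))
  })
}

#' Create a reaction entity record
#'
#' @param id Unique key.
#' @param name Optional name.
#' @param ec Character vector of EC numbers.
#' @param balance Tri-state balanced flag: `TRUE`, `FALSE` or `NA`.
#' @param xrefs Named character vector of reaction namespace accessions.
#' @param source Originating database.
#' @param participants Data frame with columns `chemical_id` (character),
#'   `stoichiometry` (non-zero integer; negative = consumed, positive =
#'   produced) and `role` (`"reactant"` or `"cofactor"`).
#' @return A list of class `"reaction_entity"`.
#' @export
reaction_entity <- function(id, name = NULL, ec = character(),
                            balance = NA, xrefs = character(),
                            source = NULL, participants = NULL) {
  if (is.null(participants)) participants <- empty_participants()
  ent <- structure(
    list(id = as.character(id), name = name, ec = as.character(ec),
         balance = balance, xrefs = as_xrefs(xrefs), source = source,
         participants = as_participants(participants)),
    class = c("reaction_entity", "kg_entity"))
  validate_entity(ent, "Reaction")
  ent
}

#' Create an enzyme entity record
#'
#' @param uniprot UniProt accession (node key), e.g. `"P0A6V8"`.
#' @param entry UniProt mnemonic entry name, e.g. `"HXKA_YEAST"`.
#' @param ec_code Character vector of EC numbers.
#' @param name Preferred name; `names` holds synonyms.
#' @param names Character vector of synonyms.
#' @return A list of class `"enzyme_entity"`.
#' @export
enzyme_entity <- function(uniprot, entry = NULL, ec_code = character(),
                          name = NULL, names = character()) {
  ent <- structure(
    list(uniprot = as.character(uniprot), entry = entry,
         ec_code = as.character(ec_code), name = name,
         names = as.character(names)),
    class = c("enzyme_entity", "kg_entity"))
  validate_entity(ent, "Enzyme")
  ent
}

#' Create an organism entity record
#'
#' @param taxonomy NCBI-taxonomy-style id string (node key).
#' @param name Scientific name.
#' @param names Character vector of synonyms and other name classes.
#' @param parent_taxonomy Parent taxon id; `NULL` only for the root.
#' @return A list of class `"organism_entity"`.
#' @export
organism_entity <- function(taxonomy, name = NULL, names = character(),
                            parent_taxonomy = NULL) {
  ent <- structure(
    list(taxonomy = as.character(taxonomy), name = name,
         names = as.character(names), parent_taxonomy = parent_taxonomy),
    class = c("organism_entity", "kg_entity"))
  validate_entity(ent, "Organism")
  ent
}

empty_participants <- function() {
  data.frame(chemical_id = character(), stoichiometry = integer(),
             role = character(), stringsAsFactors = FALSE)
}

as_participants <- function(p) {
  if (!is.data.frame(p))
    kg_validation_error("participants must be a data frame")
  if (nrow(p) == 0) return(empty_participants())
  need <- c("chemical_id", "stoichiometry", "role")
  if (!all(need %in% names(p)))
    kg_validation_error("participants need chemical_id/stoichiometry/role")
  s <- p$stoichiometry
  if (any(is.na(s)) || any(s != round(s)) || any(s == 0))
    kg_validation_error("participant stoichiometries must be non-zero integers")
  data.frame(chemical_id = as.character(p$chemical_id),
             stoichiometry = as.integer(s),
             role = match.arg(as.character(p$role),
                              c("reactant", "cofactor"),
                              several.ok = TRUE),
             stringsAsFactors = FALSE)
}

as_xrefs <- function(x) {
  x <- unlist(x)
  if (length(x) == 0) return(stats::setNames(character(), character()))
  if (is.null(names(x)) || any(names(x) == ""))
    kg_validation_error("xrefs must be a named character vector")
  stats::setNames(as.character(x), names(x))
}

entity_key <- function(entity, label) {
  k <- entity[[KEY_FIELDS[[label]]]]
  if (is.null(k) || is.na(k) || !nzchar(k))
    kg_validation_error(sprintf("%s entity is missing its key field '%s'",
                                label, KEY_FIELDS[[label]]))
  as.character(k)
}

validate_entity <- function(entity, label) {
  entity_key(entity, label)
  if (label == "Chemical") {
    if (!is.null(entity$formula)) parse_formula(entity$formula)
    if (!is.null(entity$charge) &&
        (is.na(entity$charge) || entity$charge != round(entity$charge)))
      kg_validation_error(sprintf("chemical '%s': charge must be an integer",
                                  entity$id))
    bad <- setdiff(names(entity$xrefs), CHEMICAL_NAMESPACES)
    if (length(bad) > 0)
      kg_validation_error(sprintf(
        "chemical '%s': unknown xref namespace(s): %s",
        entity$id, paste(bad, collapse = ", ")))
  } else if (label == "Reaction") {
    bad <- setdiff(names(entity$xrefs), REACTION_NAMESPACES)
    if (length(bad) > 0)
      kg_validation_error(sprintf(
        "reaction '%s': unknown xref namespace(s): %s",
        entity$id, paste(bad, collapse = ", ")))
    as_participants(entity$participants)
  }
  invisible(entity)
}

entity_label <- function(entity) {
  switch(class(entity)[1],
         chemical_entity = "Chemical", reaction_entity = "Reaction",
         enzyme_entity = "Enzyme", organism_entity = "Organism",
         kg_schema_error(sprintf("not an entity record: %s",
                                 class(entity)[1])))
}
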