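# Namespace-token normalisation. Source databases name the same external
# resource with different tokens (e.g. "KEGG COMPOUND accession" in one
# export, "kegg" in another); cross-references are only comparable for
# entity merging once every token is mapped to its canonical
# identifiers.org key. The mapping is total over the tokens emitted by the
# bundled parsers and extensible through the build config; an unknown
# token is an explicit error, never a silent pass-through.

default_namespace_map <- function() {
  list(
    Chemical = c(
      "chebi" = "chebi",
      "chebi accession" = "chebi",
      "kegg" = "kegg.compound",
      "kegg compound accession" = "kegg.compound",
      "kegg.compound" = "kegg.compound",
      "keggc" = "kegg.compound",
      "kegg drug accession" = "kegg.drug",
      "kegg.drug" = "kegg.drug",
      "kegg glycan accession" = "kegg.glycan",
      "kegg.glycan" = "kegg.glycan",
      "mnx" = "mnx",
      "mnxref" = "mnx",
      "metanetx" = "mnx",
      "metanetx.chemical" = "mnx",
      "metacyc" = "metacyc",
      "metacycm" = "metacyc",
      "hmdb" = "hmdb",
      "cas" = "cas",
      "cas registry number" = "cas",
      "bigg" = "bigg.metabolite",
      "bigg.metabolite" = "bigg.metabolite",
      "biggm" = "bigg.metabolite",
      "chemspider" = "chemspider",
      "chemidplus" = "chemidplus",
      "drugbank" = "drugbank",
      "lipidmaps" = "lipidmaps",
      "lipid maps instance accession" = "lipidmaps",
      "seed" = "seed.compound",
      "seed.compound" = "seed.compound",
      "seedm" = "seed.compound",
      "reactome" = "reactome",
      "reactomem" = "reactome",
      "knapsack" = "knapsack",
      "molbase" = "molbase",
      "pdb" = "pdb",
      "pubmed" = "pubmed",
      "resid" = "resid",
      "umbbd.compound" = "umbbd.compound",
      "unipathway" = "unipathway",
      "wikipedia.en" = "wikipedia.en",
      "wikipedia" = "wikipedia.en"),
    Reaction = c(
      "kegg" = "kegg.reaction",
      "kegg reaction accession" = "kegg.reaction",
      "kegg.reaction" = "kegg.reaction",
      "keggr" = "kegg.reaction",
      "rhea" = "rhea",
      "rhea accession" = "rhea",
      "mnx" = "mnx",
      "mnxref" = "mnx",
      "metanetx" = "mnx",
      "metanetx.reaction" = "mnx",
      "metacyc" = "metacyc",
      "metacycr" = "metacyc",
      "bigg" = "bigg.reaction",
      "bigg.reaction" = "bigg.reaction",
      "biggr" = "bigg.reaction",
      "reactome" = "reactome",
      "reactomer" = "reactome",
      "seed" = "seed",
      "seedr" = "seed")
  )
}

#' Normalise a namespace token to its identifiers.org key
#'
#' Deterministic, case-insensitive lookup; the node-label context
#' disambiguates tokens shared across domains (`"kegg"` means
#' `kegg.compound` for a Chemical but `kegg.reaction` for a Reaction).
#'
#' @param token Source-local namespace token, e.g.
#'   `"KEGG COMPOUND accession"`.
#' @param context `"Chemical"` or `"Reaction"`.
#' @param extra Optional named character vector of additional
#'   token-to-key mappings (from the build config) consulted first.
#' @return The identifiers.org namespace key.
#' @export
#' @examples
#' normalize_namespace_key("KEGG COMPOUND accession", "Chemical")
normalize_namespace_key <- function(token, context = c("Chemical",
                                                       "Reaction"),
                                    extra = NULL) {
  context <- match.arg(context)
  if (!is.character(token) || length(token) != 1 || !nzchar(token))
    kg_validation_error("namespace token must be a non-empty string")
  t <- tolower(trimws(token))
  if (!is.null(extra) && t %in% tolower(names(extra)))
    return(unname(extra[[match(t, tolower(names(extra)))]]))
  map <- default_namespace_map()[[context]]
  if (t %in% names(map)) return(unname(map[[t]]))
  kg_unmapped_namespace_error(token, context)
}
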