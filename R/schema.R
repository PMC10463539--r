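#' Knowledge-graph schema: node types and metaedges
#'
#' The package operates on typed biological knowledge graphs following the
#' BOCK schema: 10 node types (metanodes) and 17 edge types (metaedges).
#' Each metaedge is uniquely identified by its source node type, relation
#' name and target node type, and carries a short abbreviation used in
#' metapath notation (e.g. `GaBPaG` for Gene-associated-BiologicalProcess-
#' associated-Gene).
#'
#' @return `kg_node_types()` returns a data.frame with columns `name` and
#'   `abbrev` (10 rows). `kg_metaedges()` returns a data.frame with columns
#'   `abbrev`, `source`, `relation`, `target`, `directed`, `rel_char`
#'   (17 rows).
#' @examples
#' kg_node_types()
#' kg_metaedges()
#' @export
kg_node_types <- function() {
  data.frame(
    name = c("Gene", "Disease", "Phenotype", "BiologicalProcess",
             "MolecularFunction", "CellularComponent", "ProteinDomain",
             "ProteinFamily", "ProteinComplex", "OligogenicCombination"),
    abbrev = c("G", "D", "P", "BP", "MF", "CC", "PD", "PF", "PC", "OC"),
    stringsAsFactors = FALSE
  )
}

#' @rdname kg_node_types
#' @export
kg_metaedges <- function() {
  me <- rbind(
    c("GeG",   "Gene", "coexpresses",   "Gene",                  FALSE, "e"),
    c("GpG",   "Gene", "physinteracts", "Gene",                  FALSE, "p"),
    c("GsG",   "Gene", "seqsimilar",    "Gene",                  FALSE, "s"),
    c("GaP",   "Gene", "associated",    "Phenotype",             TRUE,  "a"),
    c("GaBP",  "Gene", "associated",    "BiologicalProcess",     TRUE,  "a"),
    c("GaMF",  "Gene", "associated",    "MolecularFunction",     TRUE,  "a"),
    c("GaCC",  "Gene", "associated",    "CellularComponent",     TRUE,  "a"),
    c("GuPD",  "Gene", "hasunit",       "ProteinDomain",         TRUE,  "u"),
    c("GbPF",  "Gene", "belongs",       "ProteinFamily",         TRUE,  "b"),
    c("GfPC",  "Gene", "forms",         "ProteinComplex",        TRUE,  "f"),
    c("DdP",   "Disease", "described",  "Phenotype",             TRUE,  "d"),
    c("PrP",   "Phenotype", "resembles", "Phenotype",            FALSE, "r"),
    c("BPrBP", "BiologicalProcess", "resembles", "BiologicalProcess", FALSE, "r"),
    c("MFrMF", "MolecularFunction", "resembles", "MolecularFunction", FALSE, "r"),
    c("CCrCC", "CellularComponent", "resembles", "CellularComponent", FALSE, "r"),
    c("OCiG",  "OligogenicCombination", "involves", "Gene",      TRUE,  "i"),
    c("OCcD",  "OligogenicCombination", "causes",   "Disease",   TRUE,  "c")
  )
  data.frame(
    abbrev = me[, 1], source = me[, 2], relation = me[, 3], target = me[, 4],
    directed = as.logical(me[, 5]), rel_char = me[, 6],
    stringsAsFactors = FALSE
  )
}

# Internal fast lookups --------------------------------------------------

.schema_env <- new.env(parent = emptyenv())

.node_type_tab <- function() {
  if (is.null(.schema_env$nt)) .schema_env$nt <- kg_node_types()
  .schema_env$nt
}

.metaedge_tab <- function() {
  if (is.null(.schema_env$me)) .schema_env$me <- kg_metaedges()
  .schema_env$me
}

.node_abbrev <- function(type) {
  nt <- .node_type_tab()
  nt$abbrev[match(type, nt$name)]
}

.type_from_abbrev <- function(abbrev) {
  nt <- .node_type_tab()
  nt$name[match(abbrev, nt$abbrev)]
}

.metaedge_row <- function(abbrev) {
  me <- .metaedge_tab()
  i <- match(abbrev, me$abbrev)
  if (anyNA(i)) stop("unknown metaedge abbreviation: ",
                     paste(abbrev[is.na(i)], collapse = ", "))
  me[i, , drop = FALSE]
}

.is_undirected <- function(metaedge) {
  me <- .metaedge_tab()
  !me$directed[match(metaedge, me$abbrev)]
}

# Resolve a metaedge from (type_from, rel_char, type_to) as encountered while
# walking a path left-to-right.  Returns list(abbrev, forward).  `forward` is
# FALSE when a directed metaedge is traversed against its declared direction.
.resolve_step <- function(type_from, rel_char, type_to) {
  me <- .metaedge_tab()
  fwd <- which(me$rel_char == rel_char & me$source == type_from &
                 me$target == type_to)
  if (length(fwd)) return(list(abbrev = me$abbrev[fwd[1]], forward = TRUE))
  bwd <- which(me$rel_char == rel_char & me$source == type_to &
                 me$target == type_from & me$directed)
  if (length(bwd)) return(list(abbrev = me$abbrev[bwd[1]], forward = FALSE))
  stop("no metaedge matches step ", type_from, " -", rel_char, "- ", type_to)
}
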