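#' Read and write knowledge graphs as node/edge TSV files
#'
#' The TSV dialect follows the common graph-database bulk-import layout:
#' a header row, tab separation, one node table (`uri`, `type`, one column
#' per property) and one edge table (`source`, `target`, `metaedge`,
#' `score`, `in`, one column per property). Set-valued fields (`in`) are
#' pipe-delimited. Since deposited files may use different header names,
#' `col_map` maps the expected names to the actual ones.
#'
#' @param node_file,edge_file file paths.
#' @param col_map named character vector renaming actual headers to the
#'   expected ones, e.g. `c(uri = "node_id", type = "label")`.
#' @param validate passed to [knowledge_graph()].
#' @return `read_kg_tsv()` returns a `knowledge_graph` equal to the one the
#'   GraphML reader produces from equivalent content.
#' @export
read_kg_tsv <- function(node_file, edge_file, col_map = NULL,
                        validate = TRUE) {
  rename <- function(df) {
    if (is.null(col_map)) return(df)
    for (want in names(col_map)) {
      have <- col_map[[want]]
      if (have %in% names(df)) names(df)[names(df) == have] <- want
    }
    df
  }
  nodes <- rename(utils::read.delim(node_file, stringsAsFactors = FALSE,
                                    check.names = FALSE, quote = ""))
  edges <- rename(utils::read.delim(edge_file, stringsAsFactors = FALSE,
                                    check.names = FALSE, quote = ""))
  if (!all(c("uri", "type") %in% names(nodes)))
    stop("node file must have columns uri, type (use col_map to rename)")
  if (nrow(edges) && !all(c("source", "target", "metaedge") %in% names(edges)))
    stop("edge file must have columns source, target, metaedge")
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$source, edges$target)), nodes$uri)
    if (length(missing))
      stop("referential integrity: edge endpoints missing from node file: ",
           paste(utils::head(missing, 10), collapse = ", "))
    if ("in" %in% names(edges)) {
      edges$tissues <- edges[["in"]]
      edges[["in"]] <- NULL
    }
  }
  # empty strings in optional columns mean "absent"
  for (col in setdiff(names(nodes), c("uri", "type")))
    if (is.character(nodes[[col]])) nodes[[col]][!nzchar(nodes[[col]])] <- NA
  for (col in setdiff(names(edges), c("source", "target", "metaedge")))
    if (is.character(edges[[col]])) edges[[col]][!nzchar(edges[[col]])] <- NA
  knowledge_graph(nodes, edges, validate = validate)
}

#' @rdname read_kg_tsv
#' @param kg a `knowledge_graph`.
#' @export
write_kg_tsv <- function(kg, node_file, edge_file) {
  fmt <- function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) return("")
    if (is.numeric(v)) format(v, digits = 15, scientific = FALSE, trim = TRUE)
    else as.character(v)
  }
  nprop <- sort(unique(unlist(lapply(kg$node_props, names))))
  nd <- kg$nodes[order(kg$nodes$uri), , drop = FALSE]
  ntab <- data.frame(uri = nd$uri, type = nd$type, stringsAsFactors = FALSE)
  for (nm in nprop)
    ntab[[nm]] <- vapply(nd$uri, function(u)
      fmt(kg$node_props[[u]][[nm]]), character(1))
  utils::write.table(ntab, node_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  eprop <- sort(unique(unlist(lapply(kg$edge_props, names))))
  if (nrow(kg$edges)) {
    ord <- order(kg$edges$metaedge, kg$edges$source, kg$edges$target)
  } else ord <- integer()
  ed <- kg$edges[ord, , drop = FALSE]
  etab <- data.frame(source = ed$source, target = ed$target,
                     metaedge = ed$metaedge,
                     score = vapply(ed$score, fmt, character(1)),
                     stringsAsFactors = FALSE)
  etab[["in"]] <- vapply(ord, function(i) {
    ts <- kg$edge_tissues[[i]]
    if (is.null(ts) || !length(ts)) "" else paste(ts, collapse = "|")
  }, character(1))
  for (nm in eprop)
    etab[[nm]] <- vapply(ord, function(i)
      fmt(kg$edge_props[[i]][[nm]]), character(1))
  utils::write.table(etab, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_file, edge_file))
}
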