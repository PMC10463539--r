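#' Read and write knowledge graphs in GraphML
#'
#' `read_graphml()` loads a typed knowledge graph from a GraphML file with a
#' `type` data key on nodes and a `metaedge` key on edges; `write_graphml()`
#' is its inverse. A save/load round trip is the identity on nodes, edges,
#' types, scores and properties, and re-saving a reloaded graph is
#' byte-stable (nodes are written in URI order, edges in metaedge/source/
#' target order). Edge tissue sets (the `in` property of coexpression edges)
#' are pipe-delimited.
#'
#' @param path file path.
#' @param validate passed to [knowledge_graph()].
#' @return `read_graphml()` returns a `knowledge_graph`; `write_graphml()`
#'   returns `path` invisibly.
#' @export
read_graphml <- function(path, validate = TRUE) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  key_id <- xml2::xml_attr(keys, "id")
  key_name <- xml2::xml_attr(keys, "attr.name")
  key_type <- xml2::xml_attr(keys, "attr.type")
  key_for <- xml2::xml_attr(keys, "for")
  lookup <- function(id) {
    i <- match(id, key_id)
    if (is.na(i)) list(name = id, type = "string") else
      list(name = key_name[i], type = key_type[i])
  }

  read_data <- function(el) {
    ds <- xml2::xml_find_all(el, "./g:data", ns)
    if (!length(ds)) return(list())
    vals <- xml2::xml_text(ds)
    ids <- xml2::xml_attr(ds, "key")
    out <- list()
    for (i in seq_along(ids)) {
      k <- lookup(ids[i])
      v <- vals[i]
      if (k$type %in% c("double", "float", "long", "int")) v <- as.numeric(v)
      out[[k$name]] <- v
    }
    out
  }

  nodes_xml <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  n_uri <- xml2::xml_attr(nodes_xml, "id")
  n_type <- character(length(n_uri))
  n_props <- vector("list", length(n_uri))
  for (i in seq_along(nodes_xml)) {
    d <- read_data(nodes_xml[[i]])
    if (is.null(d$type)) stop("schema error: node '", n_uri[i],
                              "' lacks a type attribute")
    n_type[i] <- d$type
    d$type <- NULL
    if (length(d)) n_props[[i]] <- d
  }

  edges_xml <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  e_src <- xml2::xml_attr(edges_xml, "source")
  e_tgt <- xml2::xml_attr(edges_xml, "target")
  m <- length(edges_xml)
  e_me <- character(m); e_score <- rep(NA_real_, m)
  e_tissues <- vector("list", m); e_props <- vector("list", m)
  for (i in seq_along(edges_xml)) {
    d <- read_data(edges_xml[[i]])
    if (is.null(d$metaedge)) stop("schema error: edge ", e_src[i], "->",
                                  e_tgt[i], " lacks a metaedge attribute")
    e_me[i] <- d$metaedge
    if (!is.null(d$score)) e_score[i] <- as.numeric(d$score)
    if (!is.null(d[["in"]]))
      e_tissues[[i]] <- sort(strsplit(d[["in"]], "|", fixed = TRUE)[[1]])
    d$metaedge <- NULL; d$score <- NULL; d[["in"]] <- NULL
    if (length(d)) e_props[[i]] <- d
  }

  nodes <- data.frame(uri = as.character(n_uri),
                      type = n_type, stringsAsFactors = FALSE)
  nodes$props <- n_props
  edges <- data.frame(source = as.character(e_src),
                      target = as.character(e_tgt),
                      metaedge = e_me, score = e_score,
                      stringsAsFactors = FALSE)
  edges$tissues <- e_tissues
  edges$props <- e_props
  knowledge_graph(nodes, edges, validate = validate)
}

#' @rdname read_graphml
#' @param kg a `knowledge_graph`.
#' @export
write_graphml <- function(kg, path) {
  num_fmt <- function(x) format(x, digits = 15, scientific = FALSE,
                                trim = TRUE)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }

  # collect property keys and their types
  nprop_names <- sort(unique(unlist(lapply(kg$node_props, names))))
  eprop_names <- sort(unique(unlist(lapply(kg$edge_props, names))))
  prop_type <- function(props, nm) {
    vals <- unlist(lapply(props, function(p) p[[nm]]), use.names = FALSE)
    if (is.numeric(vals)) "double" else "string"
  }
  ntypes <- vapply(nprop_names, function(nm) prop_type(kg$node_props, nm),
                   character(1))
  etypes <- vapply(eprop_names, function(nm) prop_type(kg$edge_props, nm),
                   character(1))

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">"),
    "  <key id=\"d0\" for=\"node\" attr.name=\"type\" attr.type=\"string\"/>",
    "  <key id=\"d1\" for=\"edge\" attr.name=\"metaedge\" attr.type=\"string\"/>",
    "  <key id=\"d2\" for=\"edge\" attr.name=\"score\" attr.type=\"double\"/>",
    "  <key id=\"d3\" for=\"edge\" attr.name=\"in\" attr.type=\"string\"/>")
  kid <- 4L
  nkey <- character(0); ekey <- character(0)
  for (i in seq_along(nprop_names)) {
    id <- paste0("d", kid); kid <- kid + 1L
    nkey[nprop_names[i]] <- id
    lines <- c(lines, paste0("  <key id=\"", id,
      "\" for=\"node\" attr.name=\"", esc(nprop_names[i]),
      "\" attr.type=\"", ntypes[i], "\"/>"))
  }
  for (i in seq_along(eprop_names)) {
    id <- paste0("d", kid); kid <- kid + 1L
    ekey[eprop_names[i]] <- id
    lines <- c(lines, paste0("  <key id=\"", id,
      "\" for=\"edge\" attr.name=\"", esc(eprop_names[i]),
      "\" attr.type=\"", etypes[i], "\"/>"))
  }
  lines <- c(lines, "  <graph id=\"KG\" edgedefault=\"directed\">")

  node_ord <- order(kg$nodes$uri)
  for (i in node_ord) {
    uri <- kg$nodes$uri[i]
    dat <- paste0("      <data key=\"d0\">", esc(kg$nodes$type[i]), "</data>")
    p <- kg$node_props[[uri]]
    for (nm in intersect(nprop_names, names(p))) {
      v <- p[[nm]]
      v <- if (is.numeric(v)) num_fmt(v) else esc(as.character(v))
      dat <- c(dat, paste0("      <data key=\"", nkey[nm], "\">", v, "</data>"))
    }
    lines <- c(lines, paste0("    <node id=\"", esc(uri), "\">"), dat,
               "    </node>")
  }

  if (nrow(kg$edges)) {
    edge_ord <- order(kg$edges$metaedge, kg$edges$source, kg$edges$target)
  } else edge_ord <- integer()
  for (i in edge_ord) {
    e <- kg$edges[i, ]
    dat <- paste0("      <data key=\"d1\">", e$metaedge, "</data>")
    if (!is.na(e$score))
      dat <- c(dat, paste0("      <data key=\"d2\">", num_fmt(e$score),
                           "</data>"))
    ts <- kg$edge_tissues[[i]]
    if (!is.null(ts) && length(ts))
      dat <- c(dat, paste0("      <data key=\"d3\">",
                           esc(paste(ts, collapse = "|")), "</data>"))
    p <- kg$edge_props[[i]]
    for (nm in intersect(eprop_names, names(p))) {
      v <- p[[nm]]
      v <- if (is.numeric(v)) num_fmt(v) else esc(as.character(v))
      dat <- c(dat, paste0("      <data key=\"", ekey[nm], "\">", v, "</data>"))
    }
    lines <- c(lines, paste0("    <edge source=\"", esc(e$source),
                             "\" target=\"", esc(e$target), "\">"),
               dat, "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
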