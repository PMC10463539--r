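#' Construct a typed knowledge graph
#'
#' Builds a schema-conformant knowledge graph from a node table and an edge
#' table. Undirected metaedges (`GeG`, `GpG`, `GsG`, `PrP`, `BPrBP`, `MFrMF`,
#' `CCrCC`) are canonicalized with their endpoints in lexicographic URI
#' order; duplicate reversed entries are merged keeping the maximum score and
#' the union of tissue sets. Multi-edges between the same node pair are
#' allowed only across distinct metaedges.
#'
#' @param nodes data.frame with columns `uri`, `type`; any further columns
#'   (e.g. `RVIS`, `GDI`) are stored as node properties. A list column
#'   `props` of named lists is also accepted.
#' @param edges data.frame with columns `source`, `target`, `metaedge` and
#'   optionally `score` (numeric in \[0,1\]) and `tissues` (list column of
#'   character vectors, or pipe-delimited strings); further columns are
#'   stored as edge properties.
#' @param validate if `TRUE` (default), stop when [validate_kg()] reports
#'   violations.
#' @return An object of class `knowledge_graph`: a list with elements
#'   `nodes` (data.frame `uri`, `type`), `node_props` (named list),
#'   `edges` (data.frame `source`, `target`, `metaedge`, `score`),
#'   `edge_tissues`, `edge_props` (lists parallel to edge rows) and a
#'   prebuilt adjacency index.
#' @examples
#' kg <- knowledge_graph(
#'   nodes = data.frame(uri = c("g1", "g2"), type = "Gene"),
#'   edges = data.frame(source = "g1", target = "g2", metaedge = "GpG",
#'                      score = 0.9)
#' )
#' kg
#' @export
knowledge_graph <- function(nodes = NULL, edges = NULL, validate = TRUE) {
  if (is.null(nodes)) nodes <- data.frame(uri = character(), type = character())
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("uri", "type") %in% names(nodes)))
    stop("`nodes` must have columns uri, type")
  nodes$uri <- as.character(nodes$uri)
  nodes$type <- as.character(nodes$type)
  if (any(!nzchar(nodes$uri))) stop("node uri must be non-empty")
  if (anyDuplicated(nodes$uri))
    stop("duplicate node uri: ", nodes$uri[duplicated(nodes$uri)][1])

  node_props <- .collect_props(nodes, c("uri", "type"))
  names(node_props) <- nodes$uri
  node_props <- node_props[!vapply(node_props, is.null, logical(1))]

  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        metaedge = character())
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && !all(c("source", "target", "metaedge") %in% names(edges)))
    stop("`edges` must have columns source, target, metaedge")
  if (!nrow(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        metaedge = character(), score = numeric())
    edge_tissues <- list(); edge_props <- list()
  } else {
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$metaedge <- as.character(edges$metaedge)
    score <- if ("score" %in% names(edges)) as.numeric(edges$score)
             else rep(NA_real_, nrow(edges))
    edge_tissues <- .as_tissue_list(edges$tissues, nrow(edges))
    edge_props <- .collect_props(edges,
      c("source", "target", "metaedge", "score", "tissues"))

    # canonicalize undirected metaedges
    und <- .is_undirected(edges$metaedge)
    und[is.na(und)] <- FALSE
    flip <- und & edges$source > edges$target
    if (any(flip)) {
      tmp <- edges$source[flip]
      edges$source[flip] <- edges$target[flip]
      edges$target[flip] <- tmp
    }
    edges <- data.frame(source = edges$source, target = edges$target,
                        metaedge = edges$metaedge, score = score,
                        stringsAsFactors = FALSE)

    key <- paste(edges$source, edges$target, edges$metaedge, sep = "\r")
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      grp <- match(key, key[keep])
      mscore <- tapply(edges$score, grp, function(s)
        if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
      mt <- lapply(split(seq_len(nrow(edges)), grp), function(i) {
        ts <- unique(unlist(edge_tissues[i]))
        if (is.null(ts) || !length(ts)) NULL else sort(ts)
      })
      edges <- edges[keep, , drop = FALSE]
      edges$score <- as.numeric(mscore)
      edge_tissues <- unname(mt)
      edge_props <- edge_props[keep]
      rownames(edges) <- NULL
    }
  }

  kg <- structure(
    list(nodes = nodes[, c("uri", "type")], node_props = node_props,
         edges = edges, edge_tissues = edge_tissues, edge_props = edge_props),
    class = "knowledge_graph")
  kg <- .kg_build_index(kg)
  if (validate) {
    rep <- validate_kg(kg)
    if (nrow(rep)) stop("schema violations:\n",
                        paste(utils::head(rep$message, 5), collapse = "\n"))
  }
  kg
}

.collect_props <- function(df, reserved) {
  extra <- setdiff(names(df), reserved)
  n <- nrow(df)
  if ("props" %in% extra) {
    props <- df$props
    extra <- setdiff(extra, "props")
  } else props <- vector("list", n)
  for (col in extra) {
    v <- df[[col]]
    for (i in seq_len(n)) {
      if (is.list(v)) { val <- v[[i]] } else val <- v[i]
      if (length(val) == 1 && !is.na(val)) props[[i]] <- c(props[[i]],
        stats::setNames(list(val), col))
    }
  }
  props
}

.as_tissue_list <- function(x, n) {
  if (is.null(x)) return(vector("list", n))
  if (is.list(x)) return(lapply(x, function(t)
    if (is.null(t) || all(is.na(t)) || !length(t)) NULL else sort(unique(as.character(t)))))
  lapply(as.character(x), function(t) {
    if (is.na(t) || !nzchar(t)) NULL else sort(unique(strsplit(t, "|", fixed = TRUE)[[1]]))
  })
}

# adjacency index: integer ids, per-node incident edge rows and neighbours
.kg_build_index <- function(kg) {
  n <- nrow(kg$nodes)
  uri_id <- stats::setNames(seq_len(n), kg$nodes$uri)
  m <- nrow(kg$edges)
  if (m) {
    si <- uri_id[kg$edges$source]
    ti <- uri_id[kg$edges$target]
    if (anyNA(si) || anyNA(ti)) {
      missing <- unique(c(kg$edges$source[is.na(si)], kg$edges$target[is.na(ti)]))
      stop("edge endpoints missing from node set: ",
           paste(utils::head(missing, 10), collapse = ", "))
    }
    ends <- c(si, ti)
    other <- c(ti, si)
    eidx <- rep(seq_len(m), 2L)
    o <- order(ends)
    adj_edge <- split(eidx[o], factor(ends[o], levels = seq_len(n)))
    adj_nb <- split(other[o], factor(ends[o], levels = seq_len(n)))
  } else {
    adj_edge <- rep(list(integer()), n)
    adj_nb <- rep(list(integer()), n)
  }
  kg$index <- list(uri_id = uri_id, type = kg$nodes$type,
                   adj_edge = unname(adj_edge), adj_nb = unname(adj_nb))
  kg
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("Knowledge graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) {
    tt <- sort(table(x$nodes$type), decreasing = TRUE)
    cat("  node types:", paste0(names(tt), " (", tt, ")", collapse = ", "), "\n")
  }
  if (nrow(x$edges)) {
    et <- sort(table(x$edges$metaedge), decreasing = TRUE)
    cat("  metaedges: ", paste0(names(et), " (", et, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a knowledge graph against the schema
#'
#' Checks every node and edge against the schema: known node types, known
#' metaedges, endpoint node types matching the metaedge declaration, and
#' scores within \[0,1\]. Violations are returned as report rows, not raised
#' as errors.
#'
#' @param kg a `knowledge_graph`.
#' @return data.frame with columns `kind`, `element`, `message`; zero rows
#'   when the graph is schema-conformant.
#' @export
validate_kg <- function(kg) {
  kinds <- character(); els <- character(); msgs <- character()
  add <- function(kind, el, msg) {
    kinds <<- c(kinds, kind); els <<- c(els, el); msgs <<- c(msgs, msg)
  }
  nt <- .node_type_tab()
  bad <- !(kg$nodes$type %in% nt$name)
  for (i in which(bad))
    add("unknown_node_type", kg$nodes$uri[i],
        paste0("node '", kg$nodes$uri[i], "' has unknown type '",
               kg$nodes$type[i], "'"))
  me <- .metaedge_tab()
  ed <- kg$edges
  if (nrow(ed)) {
    ntype <- stats::setNames(kg$nodes$type, kg$nodes$uri)
    el <- paste0(ed$source, "-", ed$metaedge, "-", ed$target)
    j <- match(ed$metaedge, me$abbrev)
    for (i in which(is.na(j)))
      add("unknown_metaedge", el[i],
          paste0("edge ", el[i], " has unknown metaedge '", ed$metaedge[i], "'"))
    known <- !is.na(j)
    st <- unname(ntype[ed$source]); tt <- unname(ntype[ed$target])
    ok <- rep(TRUE, nrow(ed))
    k <- which(known)
    ok[k] <- (st[k] == me$source[j[k]] & tt[k] == me$target[j[k]]) |
      (!me$directed[j[k]] & st[k] == me$target[j[k]] & tt[k] == me$source[j[k]])
    ok[is.na(ok)] <- FALSE
    for (i in which(known & !ok))
      add("endpoint_type", el[i],
          paste0("edge ", el[i], " endpoint types (", st[i], ", ", tt[i],
                 ") do not match metaedge ", ed$metaedge[i], " (",
                 me$source[j[i]], " -> ", me$target[j[i]], ")"))
    badscore <- !is.na(ed$score) & (ed$score < 0 | ed$score > 1)
    for (i in which(badscore))
      add("score_range", el[i],
          paste0("edge ", el[i], " score ", ed$score[i], " outside [0,1]"))
  }
  data.frame(kind = kinds, element = els, message = msgs,
             stringsAsFactors = FALSE)
}

#' Per-metaedge edge and endpoint counts
#'
#' @param kg a `knowledge_graph`.
#' @return data.frame with one row per metaedge present in the graph:
#'   `metaedge`, `n_edges`, `n_sources`, `n_targets`, ordered by decreasing
#'   edge count. For undirected metaedges source/target counts refer to the
#'   canonical stored orientation.
#' @export
metaedge_stats <- function(kg) {
  if (!nrow(kg$edges))
    return(data.frame(metaedge = character(), n_edges = integer(),
                      n_sources = integer(), n_targets = integer()))
  sp <- split(seq_len(nrow(kg$edges)), kg$edges$metaedge)
  out <- data.frame(
    metaedge = names(sp),
    n_edges = vapply(sp, length, integer(1)),
    n_sources = vapply(sp, function(i) length(unique(kg$edges$source[i])),
                       integer(1)),
    n_targets = vapply(sp, function(i) length(unique(kg$edges$target[i])),
                       integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_edges, out$metaedge), ]
  rownames(out) <- NULL
  out
}

#' Retrieve a node property
#'
#' @param kg a `knowledge_graph`.
#' @param uri node identifier.
#' @param key property name (e.g. `"RVIS"`).
#' @return the property value, or `NULL` when absent.
#' @export
kg_node_prop <- function(kg, uri, key) {
  p <- kg$node_props[[uri]]
  if (is.null(p)) return(NULL)
  p[[key]]
}
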