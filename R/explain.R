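#' Query the paths satisfying a rule for a matching gene pair
#'
#' For each condition, returns every path of its metapath with reliability
#' at or above the condition threshold; for unified rules, only paths
#' consistent with some shared unification node are retained for the two
#' unified conditions (the union over all consistent joint assignments).
#'
#' @param rule a `kg_rule`.
#' @param index a `gene_pair_paths` for a pair that matches the rule.
#' @return list (one element per condition) of lists of path objects.
#' @export
query_rule <- function(rule, index) {
  qual <- .qualifying_paths(rule, index)
  if (is.null(qual)) stop("pair does not match the rule: ",
                          format_rule(rule))
  u <- rule$unification
  if (!is.null(u)) {
    shared <- .unified_nodes(rule, index, qual)
    if (!length(shared)) stop("pair does not match the rule: ",
                              format_rule(rule))
    keep_through <- function(ids, pos) {
      at <- vapply(index$paths[ids], function(p) p$nodes[pos], character(1))
      ids[at %in% shared]
    }
    qual[[u$cond_i]] <- keep_through(qual[[u$cond_i]], u$pos_i)
    qual[[u$cond_j]] <- keep_through(qual[[u$cond_j]], u$pos_j)
  }
  lapply(qual, function(ids) index$paths[ids])
}

#' Build an explanation subgraph from rule-matching paths
#'
#' Takes the per-condition path lists returned by [query_rule()] and forms
#' the union of their nodes and edges, attaching to every edge the
#' provenance set of (rule id, condition index) pairs that traversed it.
#'
#' @param kg the `knowledge_graph` the paths came from.
#' @param paths_per_condition output of [query_rule()].
#' @param rule_id identifier recorded in the provenance (default "r1").
#' @return an object of class `explanation_subgraph`: list with `nodes`
#'   (data.frame `uri`, `type`), `edges` (data.frame `source`, `target`,
#'   `metaedge`, `score`, `provenance`), and `path_counts` per condition.
#' @export
build_explanation <- function(kg, paths_per_condition, rule_id = "r1") {
  edge_ids <- integer(); prov <- character()
  node_uris <- character()
  for (c in seq_along(paths_per_condition)) {
    for (p in paths_per_condition[[c]]) {
      edge_ids <- c(edge_ids, p$edges)
      prov <- c(prov, rep(paste0(rule_id, ":", c), length(p$edges)))
      node_uris <- c(node_uris, p$nodes)
    }
  }
  node_uris <- unique(node_uris)
  uniq <- sort(unique(edge_ids))
  prov_by_edge <- vapply(uniq, function(e)
    paste(sort(unique(prov[edge_ids == e])), collapse = ";"), character(1))
  ni <- match(node_uris, kg$nodes$uri)
  nodes <- data.frame(uri = node_uris, type = kg$nodes$type[ni],
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$uri), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(source = kg$edges$source[uniq],
                      target = kg$edges$target[uniq],
                      metaedge = kg$edges$metaedge[uniq],
                      score = kg$edges$score[uniq],
                      provenance = prov_by_edge, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 path_counts = vapply(paths_per_condition, length,
                                      integer(1))),
            class = "explanation_subgraph")
}

#' @export
print.explanation_subgraph <- function(x, ...) {
  cat("Explanation subgraph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges;", sum(x$path_counts), "paths (",
      paste(x$path_counts, collapse = " + "), ")\n")
  invisible(x)
}

#' Export an explanation subgraph to GraphML
#'
#' Node types, edge types, scores and provenance are emitted as GraphML
#' attributes; the file is reloadable with [read_graphml()].
#'
#' @param subgraph an `explanation_subgraph`.
#' @param path file path.
#' @export
write_explanation_graphml <- function(subgraph, path) {
  ed <- subgraph$edges
  ed$props <- lapply(ed$provenance, function(p) list(provenance = p))
  ed$provenance <- NULL
  kg <- knowledge_graph(subgraph$nodes, ed, validate = FALSE)
  write_graphml(kg, path)
}

#' Explain the positive prediction of a gene pair
#'
#' Runs the model on the pair and, for each matched rule (ranked by class
#' probability), queries the knowledge graph for the satisfying paths and
#' builds one explanation subgraph per rule.
#'
#' @param model a fitted `pathrules` model.
#' @param kg the `knowledge_graph`.
#' @param pair character vector of two Gene URIs.
#' @param top_n maximum number of matched rules to explain (default 5).
#' @return list with `probability`, `rules` (data.frame of matched rules
#'   with probabilities and path counts) and `explanations` (list of
#'   `explanation_subgraph`).
#' @export
explain_pair <- function(model, kg, pair, top_n = 5) {
  op <- order_gene_pair(kg, pair[1], pair[2])
  index <- enumerate_paths(kg, op, model$params$path_cutoff,
                           model$params$exclude_types)
  rp <- vapply(model$rules, function(r) r$probability, numeric(1))
  hit <- which(vapply(model$rules, rule_matches, logical(1), index = index))
  hit <- hit[order(-rp[hit])]
  hit <- utils::head(hit, top_n)
  expl <- list(); info <- list()
  for (h in seq_along(hit)) {
    r <- model$rules[[hit[h]]]
    qp <- query_rule(r, index)
    sg <- build_explanation(kg, qp, rule_id = paste0("r", hit[h]))
    expl[[h]] <- sg
    info[[h]] <- data.frame(rule = format_rule(r),
                            probability = r$probability,
                            n_paths = sum(sg$path_counts),
                            stringsAsFactors = FALSE)
  }
  prob <- if (length(hit)) rp[hit[1]] else model$default_negative_probability
  list(probability = prob,
       rules = if (length(info)) do.call(rbind, info) else
         data.frame(rule = character(), probability = numeric(),
                    n_paths = integer()),
       explanations = expl)
}
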