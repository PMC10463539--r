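#' Order a gene pair by variant intolerance
#'
#' Paths are anchored at the gene with the lowest Residual Variation
#' Intolerance Score (RVIS, node property `RVIS`) and end at the other gene.
#' Ties are broken by lexicographic URI; a gene with a missing RVIS sorts
#' after one with a value.
#'
#' @param kg a `knowledge_graph`.
#' @param gene_a,gene_b URIs of two Gene nodes.
#' @return character vector `c(source, target)`.
#' @export
order_gene_pair <- function(kg, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    i <- match(g, kg$nodes$uri)
    if (is.na(i)) stop("gene not in graph: ", g)
    if (kg$nodes$type[i] != "Gene")
      stop("node is not a Gene: ", g, " (", kg$nodes$type[i], ")")
  }
  ra <- kg_node_prop(kg, gene_a, "RVIS")
  rb <- kg_node_prop(kg, gene_b, "RVIS")
  ra <- if (is.null(ra)) NA_real_ else as.numeric(ra)
  rb <- if (is.null(rb)) NA_real_ else as.numeric(rb)
  first_a <- if (is.na(ra) && is.na(rb)) gene_a <= gene_b
    else if (is.na(ra)) FALSE
    else if (is.na(rb)) TRUE
    else if (ra != rb) ra < rb
    else gene_a <= gene_b
  if (first_a) c(gene_a, gene_b) else c(gene_b, gene_a)
}

#' Parse or render a metapath abbreviation
#'
#' A metapath abbreviation interleaves node-type abbreviations with one-letter
#' relation codes, e.g. `"GaBPaG"` (Gene -associated- BiologicalProcess
#' -associated- Gene). The node-type sequence disambiguates the traversal
#' direction of directed metaedges.
#'
#' @param abbrev a metapath abbreviation string.
#' @return `parse_metapath()` returns a list with `types` (node type
#'   sequence), `metaedges` (metaedge abbreviations per step) and `forward`
#'   (logical per step; `FALSE` when a directed metaedge is traversed
#'   against its declared direction).
#' @export
parse_metapath <- function(abbrev) {
  toks <- regmatches(abbrev, gregexpr("[A-Z]+|[a-z]", abbrev))[[1]]
  if (length(toks) < 3 || length(toks) %% 2 == 0)
    stop("malformed metapath abbreviation: ", abbrev)
  node_toks <- toks[seq(1, length(toks), by = 2)]
  rel_toks <- toks[seq(2, length(toks), by = 2)]
  types <- .type_from_abbrev(node_toks)
  if (anyNA(types))
    stop("unknown node type abbreviation in metapath: ", abbrev)
  k <- length(rel_toks)
  metaedges <- character(k); forward <- logical(k)
  for (i in seq_len(k)) {
    st <- .resolve_step(types[i], rel_toks[i], types[i + 1])
    metaedges[i] <- st$abbrev
    forward[i] <- st$forward
  }
  list(types = types, metaedges = metaedges, forward = forward)
}

# render abbreviation from node types + per-step metaedges
.metapath_abbrev <- function(types, metaedges) {
  me <- .metaedge_tab()
  rel <- me$rel_char[match(metaedges, me$abbrev)]
  ab <- .node_abbrev(types)
  paste0(paste0(ab[-length(ab)], rel, collapse = ""), ab[length(ab)])
}

#' Path reliability: geometric mean of edge scores
#'
#' Edges lacking a score contribute 1.0 (no penalty).
#'
#' @param kg a `knowledge_graph`.
#' @param edges integer vector of edge row indices in `kg$edges`.
#' @return a real in \[0,1\].
#' @export
path_reliability <- function(kg, edges) {
  s <- kg$edges$score[edges]
  s[is.na(s)] <- 1
  prod(s)^(1 / length(s))
}

#' Tissue consistency of a path
#'
#' A path crossing several coexpression (`GeG`) edges is consistent only if
#' the tissue sets recorded in their `in` properties share at least one
#' tissue. A `GeG` edge without an `in` property is treated as valid in all
#' tissues.
#'
#' @param kg a `knowledge_graph`.
#' @param edges integer vector of edge row indices.
#' @return logical flag.
#' @export
tissue_consistent <- function(kg, edges) {
  geg <- edges[kg$edges$metaedge[edges] == "GeG"]
  if (length(geg) <= 1) return(TRUE)
  sets <- kg$edge_tissues[geg]
  sets <- sets[!vapply(sets, is.null, logical(1))]  # missing => all tissues
  if (length(sets) <= 1) return(TRUE)
  common <- Reduce(intersect, sets)
  length(common) > 0
}

#' Enumerate heterogeneous paths between a gene pair
#'
#' Performs a direction-agnostic traversal of all simple paths (no repeated
#' node) of length up to `path_cutoff` from `source` to `target`, skipping
#' intermediate nodes of the excluded types and discarding
#' tissue-inconsistent paths ([tissue_consistent()]). Each retained path is
#' annotated with its metapath (the original edge directionality is encoded
#' in the type sequence) and its reliability score.
#'
#' @param kg a `knowledge_graph`.
#' @param pair character vector `c(source, target)` of Gene URIs, ordered
#'   (see [order_gene_pair()]).
#' @param path_cutoff maximum number of edges per path (default 3).
#' @param exclude_types node types never traversed as intermediates
#'   (default Disease and OligogenicCombination; add Phenotype for a
#'   phenotype-free model).
#' @return An object of class `gene_pair_paths`: list with `source`,
#'   `target`, `paths` (each a list with `nodes`, `edges`, `metapath`,
#'   `reliability`), `by_metapath` (named list of path indices) and the
#'   enumeration parameters.
#' @export
enumerate_paths <- function(kg, pair, path_cutoff = 3,
                            exclude_types = c("Disease",
                                              "OligogenicCombination")) {
  stopifnot(length(pair) == 2, path_cutoff >= 1)
  idx <- kg$index
  src <- unname(idx$uri_id[pair[1]])
  tgt <- unname(idx$uri_id[pair[2]])
  if (is.na(src)) stop("gene not in graph: ", pair[1])
  if (is.na(tgt)) stop("gene not in graph: ", pair[2])

  excluded <- idx$type %in% exclude_types
  n <- length(idx$type)
  visited <- logical(n)
  visited[src] <- TRUE
  acc_edges <- vector("list", 256L); n_acc <- 0L
  stack_e <- integer(path_cutoff)

  dfs <- function(u, depth) {
    ae <- idx$adj_edge[[u]]; an <- idx$adj_nb[[u]]
    for (k in seq_along(ae)) {
      e <- ae[k]; v <- an[k]
      stack_e[depth + 1L] <<- e
      if (v == tgt) {
        n_acc <<- n_acc + 1L
        if (n_acc > length(acc_edges))
          length(acc_edges) <<- 2L * n_acc
        acc_edges[[n_acc]] <<- stack_e[seq_len(depth + 1L)]
      } else if (depth + 1L < path_cutoff && !visited[v] && !excluded[v]) {
        visited[v] <<- TRUE
        dfs(v, depth + 1L)
        visited[v] <<- FALSE
      }
    }
  }
  dfs(src, 0L)
  raw <- if (n_acc) acc_edges[seq_len(n_acc)] else list()

  # annotate and filter
  uris <- kg$nodes$uri
  paths <- vector("list", length(raw)); np <- 0L
  for (pe in raw) {
    if (!tissue_consistent(kg, pe)) next
    # rebuild node sequence by walking the edges
    nodes <- character(length(pe) + 1L)
    nodes[1] <- pair[1]
    cur <- pair[1]
    ok <- TRUE
    for (j in seq_along(pe)) {
      e <- pe[j]
      s <- kg$edges$source[e]; t <- kg$edges$target[e]
      nxt <- if (s == cur) t else s
      nodes[j + 1L] <- nxt
      cur <- nxt
    }
    types <- idx$type[idx$uri_id[nodes]]
    mp <- .metapath_abbrev(types, kg$edges$metaedge[pe])
    np <- np + 1L
    paths[[np]] <- list(nodes = nodes, edges = pe, metapath = mp,
                        reliability = path_reliability(kg, pe))
  }
  paths <- if (np) paths[seq_len(np)] else list()

  mps <- vapply(paths, function(p) p$metapath, character(1))
  by_metapath <- if (length(mps)) split(seq_along(paths), mps) else list()
  structure(list(source = pair[1], target = pair[2], paths = paths,
                 by_metapath = by_metapath, path_cutoff = path_cutoff,
                 exclude_types = exclude_types),
            class = "gene_pair_paths")
}

#' @export
print.gene_pair_paths <- function(x, ...) {
  cat("Paths ", x$source, " -> ", x$target, ": ", length(x$paths),
      " paths over ", length(x$by_metapath), " metapaths (cutoff ",
      x$path_cutoff, ")\n", sep = "")
  if (length(x$by_metapath)) {
    cnt <- vapply(x$by_metapath, length, integer(1))
    cnt <- sort(cnt, decreasing = TRUE)
    cat("  ", paste0(names(cnt), " (", cnt, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

# vector of per-path reliabilities for one metapath of an index
.mp_reliabilities <- function(index, metapath) {
  ids <- index$by_metapath[[metapath]]
  if (is.null(ids)) return(numeric())
  vapply(index$paths[ids], function(p) p$reliability, numeric(1))
}
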