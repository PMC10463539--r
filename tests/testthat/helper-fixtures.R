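# Shared fixtures and independent oracles used across the test files.

# A small hand-built knowledge graph: 3 genes, 2 biological processes,
# 1 protein domain, 1 phenotype, with known paths between g1 and g2.
tiny_kg <- function() {
  nodes <- data.frame(
    uri = c("g1", "g2", "g3", "bp1", "bp2", "pd1", "hp1"),
    type = c("Gene", "Gene", "Gene", "BiologicalProcess",
             "BiologicalProcess", "ProteinDomain", "Phenotype"),
    stringsAsFactors = FALSE)
  nodes$props <- list(list(RVIS = -1.2), list(RVIS = 0.4), list(RVIS = 0),
                      NULL, NULL, NULL, NULL)
  edges <- data.frame(
    source   = c("g1", "g1", "g2", "g1", "g3", "g3", "g1", "g2", "g1"),
    target   = c("g2", "bp1", "bp1", "bp2", "bp2", "g2", "pd1", "pd1", "hp1"),
    metaedge = c("GpG", "GaBP", "GaBP", "GaBP", "GaBP", "GpG", "GuPD",
                 "GuPD", "GaP"),
    score    = c(0.9, 0.8, 0.7, 0.6, 0.9, 0.95, 0.5, 0.4, NA),
    stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges)
}

# Random schema-conformant graph over a handful of metaedges (<= 30 nodes),
# with scores and tissue sets, for oracle-equivalence testing.
random_kg <- function(n_genes = 8, n_bp = 4, n_mf = 3, n_pheno = 3,
                      n_edges = 40, p_tissue = 0.6) {
  nodes <- data.frame(
    uri = c(sprintf("g%02d", seq_len(n_genes)),
            sprintf("bp%02d", seq_len(n_bp)),
            sprintf("mf%02d", seq_len(n_mf)),
            sprintf("hp%02d", seq_len(n_pheno))),
    type = rep(c("Gene", "BiologicalProcess", "MolecularFunction",
                 "Phenotype"), c(n_genes, n_bp, n_mf, n_pheno)),
    stringsAsFactors = FALSE)
  nodes$props <- c(lapply(stats::rnorm(n_genes), function(r) list(RVIS = r)),
                   vector("list", n_bp + n_mf + n_pheno))
  by_type <- split(nodes$uri, nodes$type)
  me <- kg_metaedges()
  pool <- c("GpG", "GeG", "GsG", "GaBP", "GaMF", "GaP", "PrP", "BPrBP",
            "MFrMF")
  src <- character(); tgt <- character(); mab <- character()
  while (length(src) < n_edges) {
    ab <- sample(pool, 1)
    row <- me[me$abbrev == ab, ]
    s <- sample(by_type[[row$source]], 1)
    t <- sample(by_type[[row$target]], 1)
    if (s == t) next
    src <- c(src, s); tgt <- c(tgt, t); mab <- c(mab, ab)
  }
  edges <- data.frame(source = src, target = tgt, metaedge = mab,
                      score = round(stats::runif(n_edges), 3),
                      stringsAsFactors = FALSE)
  tset <- c("brain", "liver", "heart")
  edges$tissues <- lapply(seq_len(n_edges), function(i) {
    if (edges$metaedge[i] == "GeG" && stats::runif(1) < p_tissue)
      sort(sample(tset, sample(1:2, 1)))
    else NULL
  })
  knowledge_graph(nodes, edges)
}

# ---- independent path-enumeration oracle ------------------------------
# Exhaustive recursion over the raw edge table (no use of the package's
# adjacency index or metapath machinery). Returns a sorted character
# vector of path signatures "node/node/...|metapathAbbrev".
oracle_paths <- function(kg, src, tgt, cutoff,
                         exclude = c("Disease", "OligogenicCombination")) {
  ed <- kg$edges
  nt <- stats::setNames(kg$nodes$type, kg$nodes$uri)
  me <- kg_metaedges()
  abbr <- stats::setNames(kg_node_types()$abbrev, kg_node_types()$name)
  res <- character()
  recurse <- function(cur, nodes_so_far, edges_so_far) {
    if (length(edges_so_far) >= cutoff) return()
    inc <- which(ed$source == cur | ed$target == cur)
    for (e in inc) {
      nxt <- if (ed$source[e] == cur) ed$target[e] else ed$source[e]
      if (nxt %in% nodes_so_far) next
      if (nxt == tgt) {
        path_nodes <- c(nodes_so_far, nxt)
        path_edges <- c(edges_so_far, e)
        # tissue consistency across GeG edges
        geg <- path_edges[ed$metaedge[path_edges] == "GeG"]
        sets <- kg$edge_tissues[geg]
        sets <- sets[!vapply(sets, is.null, logical(1))]
        if (length(sets) > 1 && length(Reduce(intersect, sets)) == 0) next
        # independent metapath rendering
        mp <- abbr[[nt[[path_nodes[1]]]]]
        for (k in seq_along(path_edges)) {
          rel <- me$rel_char[me$abbrev == ed$metaedge[path_edges[k]]]
          mp <- paste0(mp, rel, abbr[[nt[[path_nodes[k + 1]]]]])
        }
        res <<- c(res, paste0(paste(path_nodes, collapse = "/"), "|", mp))
      } else if (!(nt[[nxt]] %in% exclude)) {
        recurse(nxt, c(nodes_so_far, nxt), c(edges_so_far, e))
      }
    }
  }
  recurse(src, src, integer())
  sort(res)
}

# ---- independent itemset-mining oracle --------------------------------
# Enumerates every subset of the item universe up to max_len and computes
# weighted supports directly.
oracle_itemsets <- function(item_lists, weights, minsup, max_len) {
  universe <- sort(unique(unlist(item_lists)))
  W <- sum(weights)
  out <- list()
  for (k in seq_len(min(max_len, length(universe)))) {
    sets <- utils::combn(universe, k, simplify = FALSE)
    for (s in sets) {
      sup <- sum(weights[vapply(item_lists, function(it) all(s %in% it),
                                logical(1))]) / W
      if (sup >= minsup - 1e-12)
        out[[paste(s, collapse = "\r")]] <- list(items = s, support = sup)
    }
  }
  out[order(names(out))]
}

# transaction set with given item lists but no real path indexes
fake_transactions <- function(item_lists, weights = NULL) {
  idx <- lapply(item_lists, function(it) {
    paths <- lapply(seq_along(it), function(i)
      list(nodes = c("a", paste0("x", i), "b"), edges = integer(),
           metapath = it[i], reliability = 1))
    structure(list(source = "a", target = "b", paths = paths,
                   by_metapath = stats::setNames(as.list(seq_along(it)),
                                                 it)),
              class = "gene_pair_paths")
  })
  build_transactions(idx, weights)
}

# ---- independent explanation-soundness checker ------------------------
# Re-verifies a returned path against its condition (metapath rendering,
# endpoint chaining, reliability threshold) without the package's matcher.
check_path <- function(kg, path, metapath, threshold) {
  nt <- stats::setNames(kg$nodes$type, kg$nodes$uri)
  me <- kg_metaedges()
  abbr <- stats::setNames(kg_node_types()$abbrev, kg_node_types()$name)
  mp <- abbr[[nt[[path$nodes[1]]]]]
  s <- kg$edges$score[path$edges]
  s[is.na(s)] <- 1
  for (k in seq_along(path$edges)) {
    e <- path$edges[k]
    ok <- (kg$edges$source[e] == path$nodes[k] &&
             kg$edges$target[e] == path$nodes[k + 1]) ||
      (kg$edges$target[e] == path$nodes[k] &&
         kg$edges$source[e] == path$nodes[k + 1])
    if (!ok) return(FALSE)
    rel <- me$rel_char[me$abbrev == kg$edges$metaedge[e]]
    mp <- paste0(mp, rel, abbr[[nt[[path$nodes[k + 1]]]]])
  }
  mp == metapath && prod(s)^(1 / length(s)) >= threshold - 1e-9
}

# a small planted study used by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_positive = 40, n_negative = 300, seed = 11)
      cache <<- simulate_kg(cfg)
    }
    cache
  }
})
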