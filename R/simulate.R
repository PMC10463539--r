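#' Configuration for the synthetic knowledge-graph generator
#'
#' Defines a schema-conformant synthetic study: node counts per type,
#' background edge counts per metaedge (Erdos-Renyi style with
#' Beta-distributed scores), a set of planted metapath patterns (including
#' at most one unification each), labelled gene-pair set sizes, and the
#' planting probabilities. Positive pairs receive each full planted pattern
#' with probability `p_pos` and negative pairs with probability `p_neg`;
#' in addition, every pair receives each *single condition* of the
#' multi-condition patterns with probability `decoy_prob`, emulating the
#' partial biological context (shared annotations, similarity edges) that
#' neutral pairs exhibit without the full coordinated pattern.
#'
#' @param n_genes,n_bp,n_mf,n_cc,n_pd,n_pf,n_pc,n_phenotype,n_disease,n_oc
#'   node counts per type.
#' @param bg_edges named integer vector of background edge counts per
#'   metaedge.
#' @param patterns list of planted patterns; each a list with `conditions`
#'   (metapath abbreviations), optional `unification` (as in [new_rule()])
#'   and optional `reliability` range (default `c(0.7, 1)`).
#' @param n_positive,n_negative numbers of labelled gene pairs.
#' @param p_pos,p_neg full-pattern planting probabilities (requires
#'   `p_pos > p_neg`).
#' @param decoy_prob single-condition planting probability (any class).
#' @param score_shape Beta shape parameters for background edge scores.
#' @param tissues tissue name pool for coexpression edges.
#' @param seed integer seed; the generated study is a pure function of the
#'   configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100, n_bp = 40, n_mf = 25, n_cc = 20,
                       n_pd = 20, n_pf = 20, n_pc = 15, n_phenotype = 25,
                       n_disease = 6, n_oc = 5,
                       bg_edges = c(GpG = 80, GeG = 60, GsG = 50,
                                    GaBP = 150, GaMF = 80, GaCC = 60,
                                    GuPD = 60, GbPF = 50, GfPC = 40,
                                    GaP = 80, DdP = 12, PrP = 25,
                                    BPrBP = 35, MFrMF = 15, CCrCC = 10,
                                    OCiG = 10, OCcD = 5),
                       patterns = list(
                         list(conditions = "GuPDuG"),
                         list(conditions = c("GbPFbG", "GfPCfG")),
                         list(conditions = c("GaMFaG", "GaMFrMFaG"),
                              unification = list(cond_i = 1, pos_i = 2,
                                                 cond_j = 2, pos_j = 2))),
                       n_positive = 150, n_negative = 1500,
                       p_pos = 0.8, p_neg = 0.002, decoy_prob = 0.05,
                       score_shape = c(2, 2),
                       tissues = c("brain", "heart", "liver", "lung",
                                   "kidney", "muscle"),
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_bp = n_bp, n_mf = n_mf, n_cc = n_cc,
              n_pd = n_pd, n_pf = n_pf, n_pc = n_pc,
              n_phenotype = n_phenotype, n_disease = n_disease,
              n_oc = n_oc, bg_edges = bg_edges, patterns = patterns,
              n_positive = n_positive, n_negative = n_negative,
              p_pos = p_pos, p_neg = p_neg, decoy_prob = decoy_prob,
              score_shape = score_shape, tissues = tissues, seed = seed)
  class(cfg) <- "sim_config"
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  if (cfg$p_pos <= cfg$p_neg)
    stop("invalid configuration: p_pos must exceed p_neg")
  if (any(cfg$bg_edges < 0)) stop("negative background edge count")
  bad <- setdiff(names(cfg$bg_edges), kg_metaedges()$abbrev)
  if (length(bad)) stop("unknown metaedge in bg_edges: ",
                        paste(bad, collapse = ", "))
  npairs <- choose(cfg$n_genes, 2)
  if (cfg$n_positive + cfg$n_negative > npairs)
    stop("more labelled pairs requested than distinct gene pairs exist")
  for (p in cfg$patterns)
    new_rule(p$conditions, unification = p$unification)  # schema check
  invisible(cfg)
}

.sim_type_counts <- function(cfg) {
  c(Gene = cfg$n_genes, BiologicalProcess = cfg$n_bp,
    MolecularFunction = cfg$n_mf, CellularComponent = cfg$n_cc,
    ProteinDomain = cfg$n_pd, ProteinFamily = cfg$n_pf,
    ProteinComplex = cfg$n_pc, Phenotype = cfg$n_phenotype,
    Disease = cfg$n_disease, OligogenicCombination = cfg$n_oc)
}

# edge rows for one planted pattern instance; `env` collects rows and
# holds the fresh-node counter
.plant_rows <- function(env, pair, conditions, unification, reliability,
                        gene_pool, tag) {
  shared <- NULL
  for (ci in seq_along(conditions)) {
    mp <- parse_metapath(conditions[ci])
    nodes <- character(length(mp$types))
    nodes[1] <- pair[1]
    nodes[length(nodes)] <- pair[2]
    for (pos in seq_along(nodes)[-c(1, length(nodes))]) {
      is_shared <- !is.null(unification) &&
        ((ci == unification$cond_i && pos == unification$pos_i) ||
           (ci == unification$cond_j && pos == unification$pos_j))
      if (is_shared && !is.null(shared)) {
        nodes[pos] <- shared
        next
      }
      if (mp$types[pos] == "Gene") {
        nodes[pos] <- sample(setdiff(gene_pool, c(pair, nodes)), 1)
      } else {
        env$counter <- env$counter + 1L
        uri <- paste0(tolower(.node_abbrev(mp$types[pos])), ":sim_", tag,
                      "_", env$counter)
        env$new_nodes[[length(env$new_nodes) + 1L]] <-
          c(uri = uri, type = mp$types[pos])
        nodes[pos] <- uri
      }
      if (is_shared) shared <- nodes[pos]
    }
    for (s in seq_along(mp$metaedges)) {
      a <- nodes[s]; b <- nodes[s + 1]
      if (!mp$forward[s]) { tmp <- a; a <- b; b <- tmp }
      env$new_edges[[length(env$new_edges) + 1L]] <-
        list(source = a, target = b, metaedge = mp$metaedges[s],
             score = stats::runif(1, reliability[1], reliability[2]))
    }
  }
  invisible(env)
}

#' Generate a synthetic labelled knowledge-graph study
#'
#' Builds a schema-conformant knowledge graph with background edges,
#' samples disjoint positive and negative gene pairs, plants the configured
#' metapath patterns (full patterns with probability `p_pos` in positives
#' and `p_neg` in negatives; single-condition decoys with probability
#' `decoy_prob` in all pairs), and returns the graph together with the
#' labelled pair tables and the ground-truth rules. Fully reproducible from
#' the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `kg` (a validated `knowledge_graph`),
#'   `positives` and `negatives` (data.frames `gene_a`, `gene_b`,
#'   `weight`), `truth` (list of ground-truth `kg_rule`) and `config`.
#' @export
simulate_kg <- function(config = sim_config()) {
  .validate_sim_config(config)
  set.seed(config$seed)
  cnt <- .sim_type_counts(config)
  prefix <- c(Gene = "gene", BiologicalProcess = "bp",
              MolecularFunction = "mf", CellularComponent = "cc",
              ProteinDomain = "pd", ProteinFamily = "pf",
              ProteinComplex = "pc", Phenotype = "hp", Disease = "dis",
              OligogenicCombination = "oc")
  nodes <- do.call(rbind, lapply(names(cnt), function(tp) {
    if (cnt[[tp]] == 0) return(NULL)
    data.frame(uri = sprintf("%s:%03d", prefix[[tp]], seq_len(cnt[[tp]])),
               type = tp, stringsAsFactors = FALSE)
  }))
  genes <- nodes$uri[nodes$type == "Gene"]
  rvis <- stats::rnorm(length(genes))
  node_props <- lapply(seq_along(genes), function(i) list(RVIS = rvis[i]))
  nodes$props <- c(node_props,
                   vector("list", nrow(nodes) - length(genes)))

  uris_by_type <- split(nodes$uri, nodes$type)
  me <- kg_metaedges()
  bg <- list()
  for (meab in names(config$bg_edges)) {
    n <- config$bg_edges[[meab]]
    if (n == 0) next
    row <- me[me$abbrev == meab, ]
    su <- uris_by_type[[row$source]]; tu <- uris_by_type[[row$target]]
    if (is.null(su) || is.null(tu) || !length(su) || !length(tu)) next
    src <- sample(su, 3 * n, replace = TRUE)
    tgt <- sample(tu, 3 * n, replace = TRUE)
    ok <- src != tgt
    src <- src[ok]; tgt <- tgt[ok]
    if (!row$directed) {  # canonical order for dedup
      a <- pmin(src, tgt); b <- pmax(src, tgt); src <- a; tgt <- b
    }
    keep <- !duplicated(paste(src, tgt))
    src <- src[keep][seq_len(min(n, sum(keep)))]
    tgt <- tgt[keep][seq_len(min(n, sum(keep)))]
    ed <- data.frame(source = src, target = tgt, metaedge = meab,
                     score = stats::rbeta(length(src), config$score_shape[1],
                                          config$score_shape[2]),
                     stringsAsFactors = FALSE)
    if (meab == "GeG")
      ed$tissues <- lapply(seq_len(nrow(ed)), function(i)
        sort(sample(config$tissues, sample(1:3, 1))))
    bg[[meab]] <- ed
  }

  # labelled pairs: disjoint random unordered gene pairs
  n_pairs <- config$n_positive + config$n_negative
  pick <- sample(choose(length(genes), 2), n_pairs)
  all_pairs <- utils::combn(length(genes), 2)
  gp <- all_pairs[, pick, drop = FALSE]
  pair_a <- genes[gp[1, ]]; pair_b <- genes[gp[2, ]]
  is_pos <- seq_len(n_pairs) <= config$n_positive

  # RVIS ordering for planting direction-sensitive patterns
  rv <- stats::setNames(rvis, genes)
  ordered <- function(a, b) {
    if (rv[[a]] < rv[[b]] || (rv[[a]] == rv[[b]] && a <= b)) c(a, b)
    else c(b, a)
  }

  env <- new.env(parent = emptyenv())
  env$counter <- 0L; env$new_nodes <- list(); env$new_edges <- list()
  truth <- lapply(config$patterns, function(p)
    new_rule(p$conditions, unification = p$unification))
  for (i in seq_len(n_pairs)) {
    op <- ordered(pair_a[i], pair_b[i])
    p_full <- if (is_pos[i]) config$p_pos else config$p_neg
    for (k in seq_along(config$patterns)) {
      pat <- config$patterns[[k]]
      rel <- pat$reliability %||% c(0.7, 1)
      if (stats::runif(1) < p_full)
        .plant_rows(env, op, pat$conditions, pat$unification, rel,
                    genes, paste0("p", i, "k", k))
      if (length(pat$conditions) > 1) {
        for (ci in seq_along(pat$conditions)) {
          if (stats::runif(1) < config$decoy_prob)
            .plant_rows(env, op, pat$conditions[ci], NULL, rel,
                        genes, paste0("d", i, "k", k, "c", ci))
        }
      }
    }
  }

  extra_nodes <- if (length(env$new_nodes)) {
    en <- do.call(rbind, env$new_nodes)
    data.frame(uri = en[, "uri"], type = en[, "type"],
               stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(extra_nodes)) {
    extra_nodes <- extra_nodes[!duplicated(extra_nodes$uri), , drop = FALSE]
    extra_nodes$props <- vector("list", nrow(extra_nodes))
    nodes <- rbind(nodes, extra_nodes)
  }
  edges <- do.call(rbind, c(
    lapply(bg, function(e) {
      e2 <- e[, c("source", "target", "metaedge", "score")]
      e2$tissues <- if ("tissues" %in% names(e)) e$tissues
                    else vector("list", nrow(e))
      e2
    }),
    list({
      pe <- do.call(rbind, lapply(env$new_edges, function(x)
        data.frame(source = x$source, target = x$target,
                   metaedge = x$metaedge, score = x$score,
                   stringsAsFactors = FALSE)))
      if (is.null(pe)) NULL else {
        pe$tissues <- vector("list", nrow(pe))
        pe
      }
    })))
  kg <- knowledge_graph(nodes, edges, validate = TRUE)

  list(kg = kg,
       positives = data.frame(gene_a = pair_a[is_pos],
                              gene_b = pair_b[is_pos],
                              weight = 1, stringsAsFactors = FALSE),
       negatives = data.frame(gene_a = pair_a[!is_pos],
                              gene_b = pair_b[!is_pos],
                              weight = stats::runif(sum(!is_pos), 0.3, 1),
                              stringsAsFactors = FALSE),
       truth = truth, config = config)
}

#' Plant a metapath pattern between a gene pair
#'
#' Mutates a knowledge graph so that the rule formed by `metapaths` (and
#' the optional unification) matches the pair: fresh intermediate term
#' nodes are created, intermediate Gene positions reuse existing genes,
#' and every planted edge is scored uniformly within `reliability`, so the
#' planted paths' reliabilities lie within that range.
#'
#' @param kg a `knowledge_graph`.
#' @param pair character vector of two Gene URIs (will be RVIS-ordered).
#' @param metapaths character vector of metapath abbreviations.
#' @param unification optional unification (as in [new_rule()]).
#' @param reliability numeric range for planted edge scores.
#' @param seed optional seed.
#' @return the mutated `knowledge_graph`.
#' @export
plant_pattern <- function(kg, pair, metapaths, unification = NULL,
                          reliability = c(0.7, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  op <- order_gene_pair(kg, pair[1], pair[2])
  genes <- kg$nodes$uri[kg$nodes$type == "Gene"]
  env <- new.env(parent = emptyenv())
  env$counter <- 0L; env$new_nodes <- list(); env$new_edges <- list()
  tag <- paste0("m", sample.int(1e6, 1))
  .plant_rows(env, op, metapaths, unification, reliability, genes, tag)
  nodes <- kg$nodes
  nodes$props <- unname(kg$node_props[nodes$uri])
  if (length(env$new_nodes)) {
    en <- do.call(rbind, env$new_nodes)
    extra <- data.frame(uri = en[, "uri"], type = en[, "type"],
                        stringsAsFactors = FALSE)
    extra <- extra[!duplicated(extra$uri), , drop = FALSE]
    extra$props <- vector("list", nrow(extra))
    nodes <- rbind(nodes, extra)
  }
  edges <- kg$edges
  edges$tissues <- kg$edge_tissues
  edges$props <- kg$edge_props
  pe <- do.call(rbind, lapply(env$new_edges, function(x)
    data.frame(source = x$source, target = x$target, metaedge = x$metaedge,
               score = x$score, stringsAsFactors = FALSE)))
  pe$tissues <- vector("list", nrow(pe))
  pe$props <- vector("list", nrow(pe))
  knowledge_graph(nodes, rbind(edges, pe), validate = TRUE)
}
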