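#' Ontology term hierarchy with gene annotations
#'
#' Holds an is-a directed acyclic graph over annotation terms together with
#' direct term-to-gene annotations, as used for functional-information and
#' semantic-similarity edge scoring.
#'
#' @param terms character vector of term ids.
#' @param parents data.frame with columns `child`, `parent` (is-a edges).
#' @param annotations named list mapping term id to a character vector of
#'   annotated gene ids.
#' @return an object of class `ontology_hierarchy`.
#' @export
ontology_hierarchy <- function(terms, parents = NULL, annotations = list()) {
  terms <- unique(as.character(terms))
  if (is.null(parents))
    parents <- data.frame(child = character(), parent = character())
  stopifnot(all(parents$child %in% terms), all(parents$parent %in% terms))
  if (length(annotations) && !all(names(annotations) %in% terms))
    stop("annotated term not in hierarchy: ",
         paste(setdiff(names(annotations), terms), collapse = ", "))
  # cycle check by iterated leaf stripping (Kahn)
  kids <- split(as.character(parents$child), as.character(parents$parent))
  indeg <- table(factor(as.character(parents$child), levels = terms))
  queue <- terms[indeg == 0]
  seen <- 0L
  indeg <- as.integer(indeg); names(indeg) <- terms
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (k in kids[[t]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (seen < length(terms)) stop("is-a relation contains a cycle")
  structure(list(terms = terms,
                 parent_of = split(as.character(parents$parent),
                                   as.character(parents$child)),
                 child_of = kids,
                 annotations = lapply(annotations, as.character)),
            class = "ontology_hierarchy")
}

#' Ancestors or descendants of a term (inclusive)
#'
#' @param hierarchy an `ontology_hierarchy`.
#' @param term a term id.
#' @return character vector of term ids including `term` itself.
#' @export
term_ancestors <- function(hierarchy, term) {
  .closure(hierarchy$parent_of, term)
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(hierarchy, term) {
  .closure(hierarchy$child_of, term)
}

.closure <- function(rel, term) {
  out <- character(); frontier <- term
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(unique(unlist(rel[frontier], use.names = FALSE)), out)
  }
  unique(out)
}

#' Functional information of an annotation term
#'
#' The information content of a term, scaled into \[0,1\] by the maximum
#' information content: `-log(|g(t + subterms)| / |g(T)|) / log(|g(T)|)`,
#' where `g(t)` are the genes annotated to `t` (inclusive of all subterms)
#' and `g(T)` the genes annotated to any term of the hierarchy. Rare terms
#' score close to 1, ubiquitous terms close to 0. The logarithm base
#' cancels in the ratio.
#'
#' @param term a term id.
#' @param hierarchy an `ontology_hierarchy`.
#' @return a real in \[0,1\].
#' @export
functional_information <- function(term, hierarchy) {
  if (!term %in% hierarchy$terms) stop("term not in hierarchy: ", term)
  all_genes <- unique(unlist(hierarchy$annotations, use.names = FALSE))
  if (!length(all_genes)) stop("hierarchy has no annotated gene")
  sub <- term_descendants(hierarchy, term)
  g <- unique(unlist(hierarchy$annotations[sub], use.names = FALSE))
  if (!length(g))
    stop("functional information undefined: term '", term,
         "' (with subterms) annotates no gene")
  -log(length(g) / length(all_genes)) / log(length(all_genes))
}

#' SimGIC semantic similarity between two terms
#'
#' Graph-information-content similarity: the sum of information contents
#' over the shared ancestors (inclusive of the terms) divided by the sum
#' over the union of ancestors. A `resembles` edge is emitted between terms
#' whose similarity exceeds 0.5.
#'
#' @param term_a,term_b term ids.
#' @param hierarchy an `ontology_hierarchy`.
#' @param ic named numeric vector of per-term information contents.
#' @return a real in \[0,1\].
#' @export
simgic <- function(term_a, term_b, hierarchy, ic) {
  anc_a <- term_ancestors(hierarchy, term_a)
  anc_b <- term_ancestors(hierarchy, term_b)
  inter <- intersect(anc_a, anc_b)
  uni <- union(anc_a, anc_b)
  den <- sum(ic[uni], na.rm = TRUE)
  if (den == 0) stop("similarity undefined: union information content is 0")
  sum(ic[inter], na.rm = TRUE) / den
}

#' BLAST score ratio with coverage gate
#'
#' Bit score of the pairwise alignment normalized by the smaller
#' self-alignment score, clamped to \[0,1\]. Alignments covering less than
#' half of the shorter protein are rejected (`NA`); edges are emitted for
#' ratios of at least 0.2.
#'
#' @param bitscore_ab alignment bit score between the two proteins.
#' @param self_a,self_b self-alignment bit scores (must be positive).
#' @param coverage_fraction alignment coverage of the shorter protein.
#' @return the ratio in \[0,1\], or `NA` when the coverage gate fails.
#' @export
blast_score_ratio <- function(bitscore_ab, self_a, self_b,
                              coverage_fraction) {
  if (self_a <= 0 || self_b <= 0) stop("self-alignment scores must be > 0")
  if (coverage_fraction < 0.5) return(NA_real_)
  min(1, bitscore_ab / min(self_a, self_b))
}

#' Filter tissue co-expression records into coexpression edges
#'
#' Applies the co-expression gates — minimum tissue sample size, per-gene
#' expression z-score floor, adjusted p-value ceiling and correlation floor
#' (the correlation threshold is relaxed for large tissues through the
#' Fisher transformation: `atanh(rho) >= atanh(min_rho) - z_crit/sqrt(n-3)`)
#' — then groups surviving records per gene pair into one `GeG` edge scored
#' by the maximum correlation across tissues, with the surviving tissue set
#' in the `in` property.
#'
#' @param records data.frame with columns `gene_a`, `gene_b`, `tissue`,
#'   `rho`, `adj_p`, `n_samples`, `z_a`, `z_b`.
#' @param min_rho correlation floor (default 0.80).
#' @param max_adj_p adjusted p-value ceiling (default 0.01).
#' @param min_samples minimum tissue sample count (default 70).
#' @param min_z per-gene expression z-score floor (default -3).
#' @param fisher_alpha significance level of the Fisher-transform
#'   allowance; `NULL` disables the sample-size adjustment.
#' @return data.frame of edges: `source`, `target`, `metaedge` (`GeG`),
#'   `score`, and list column `tissues`.
#' @export
filter_coexpression <- function(records, min_rho = 0.80, max_adj_p = 0.01,
                                min_samples = 70, min_z = -3,
                                fisher_alpha = 0.05) {
  r <- records
  keep <- r$n_samples >= min_samples &
    r$z_a > min_z & r$z_b > min_z &
    r$adj_p < max_adj_p
  if (is.null(fisher_alpha)) {
    keep <- keep & r$rho >= min_rho
  } else {
    zc <- stats::qnorm(1 - fisher_alpha)
    slack <- ifelse(r$n_samples > 3, zc / sqrt(r$n_samples - 3), Inf)
    keep <- keep & atanh(pmin(r$rho, 1 - 1e-12)) >= atanh(min_rho) - slack &
      r$rho > 0
  }
  r <- r[keep & !is.na(keep), , drop = FALSE]
  if (!nrow(r))
    return(data.frame(source = character(), target = character(),
                      metaedge = character(), score = numeric()))
  a <- pmin(r$gene_a, r$gene_b); b <- pmax(r$gene_a, r$gene_b)
  key <- paste(a, b, sep = "\r")
  sp <- split(seq_len(nrow(r)), key)
  out <- data.frame(
    source = vapply(sp, function(i) a[i[1]], character(1)),
    target = vapply(sp, function(i) b[i[1]], character(1)),
    metaedge = "GeG",
    score = vapply(sp, function(i) max(r$rho[i]), numeric(1)),
    stringsAsFactors = FALSE)
  out$tissues <- lapply(sp, function(i) sort(unique(r$tissue[i])))
  rownames(out) <- NULL
  out
}

#' Collapse protein-level edges to gene-level edges
#'
#' Maps each protein endpoint to its gene and keeps one edge per
#' (gene pair, metaedge) scored by the maximum over the contributing
#' protein edges. Edges collapsing into a single gene (self-edges) are
#' dropped; edges with an unmapped protein are skipped with a warning and
#' counted in the report attached as attribute `"report"`.
#'
#' @param protein_edges data.frame with columns `source`, `target`,
#'   `metaedge`, `score` (protein identifiers as endpoints).
#' @param protein_to_gene named character vector mapping protein id to
#'   gene id.
#' @return data.frame of gene-level edges (`source`, `target`, `metaedge`,
#'   `score`), endpoints in lexicographic order.
#' @export
collapse_to_genes <- function(protein_edges, protein_to_gene) {
  ga <- unname(protein_to_gene[protein_edges$source])
  gb <- unname(protein_to_gene[protein_edges$target])
  unmapped <- is.na(ga) | is.na(gb)
  if (any(unmapped))
    warning(sum(unmapped), " edge(s) skipped: unmapped protein(s) ",
            paste(utils::head(unique(c(
              protein_edges$source[is.na(ga)],
              protein_edges$target[is.na(gb)])), 5), collapse = ", "))
  e <- protein_edges[!unmapped, , drop = FALSE]
  ga <- ga[!unmapped]; gb <- gb[!unmapped]
  selfe <- ga == gb
  e <- e[!selfe, , drop = FALSE]
  a <- pmin(ga[!selfe], gb[!selfe]); b <- pmax(ga[!selfe], gb[!selfe])
  key <- paste(a, b, e$metaedge, sep = "\r")
  sp <- split(seq_along(key), key)
  out <- data.frame(
    source = vapply(sp, function(i) a[i[1]], character(1)),
    target = vapply(sp, function(i) b[i[1]], character(1)),
    metaedge = vapply(sp, function(i) e$metaedge[i[1]], character(1)),
    score = vapply(sp, function(i)
      if (all(is.na(e$score[i]))) NA_real_ else max(e$score[i], na.rm = TRUE),
      numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "report") <- c(input = nrow(protein_edges),
                           unmapped = sum(unmapped),
                           self = sum(selfe), output = nrow(out))
  out
}
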