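#' ROC points of a score vector
#'
#' @param scores predicted probabilities.
#' @param labels logical or 0/1 vector (TRUE = positive).
#' @return data.frame with columns `threshold`, `sensitivity` (TPR),
#'   `specificity`, `fpr`, in decreasing threshold order.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels); N <- sum(!labels)
  sens <- vapply(th, function(t) sum(scores >= t & labels) / max(P, 1),
                 numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !labels) / max(N, 1),
                numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = 1 - fpr,
             fpr = fpr)
}

#' Precision-recall points of a score vector
#'
#' @inheritParams roc_points
#' @return data.frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  rec <- vapply(th, function(t) sum(scores >= t & labels) / max(P, 1),
                numeric(1))
  prec <- vapply(th, function(t) {
    n <- sum(scores >= t)
    if (n == 0) 1 else sum(scores >= t & labels) / n
  }, numeric(1))
  data.frame(threshold = c(Inf, th), recall = c(0, rec),
             precision = c(if (length(prec)) prec[1] else 1, prec))
}

.trapezoid <- function(x, y) {
  o <- order(x)
  sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
}

#' Stratified k-fold cross-validation of the path-rule classifier
#'
#' Splits positives and negatives separately into `k` folds (preserving
#' the class ratio), re-runs the entire training workflow (mining,
#' optional threshold optimization, decision-set selection) on each
#' training fold only, and scores the held-out fold, so no test information
#' leaks into rule discovery.
#'
#' @param kg a `knowledge_graph`.
#' @param positives,negatives labelled pair data.frames (`gene_a`,
#'   `gene_b`, optional `weight`).
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param indexes optional precomputed `list(positive=, negative=)` path
#'   indexes (path enumeration is per-pair and therefore leakage-free).
#' @param ... further arguments to [pathrules()].
#' @return list of per-fold results, each with `fold`, `predictions`
#'   (data.frame `probability`, `label`, `weight`), `auroc`, `auprc`,
#'   `roc`, `pr`, and `rules` (serialized selected rules).
#' @export
stratified_cv <- function(kg, positives, negatives, k = 10, seed = NULL,
                          indexes = NULL, ...) {
  if (!nrow(positives) || !nrow(negatives))
    stop("both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(indexes)) {
    dots <- list(...)
    pc <- dots$path_cutoff %||% 3
    ex <- dots$exclude_types %||% c("Disease", "OligogenicCombination")
    indexes <- list(positive = pair_path_indexes(kg, positives, pc, ex),
                    negative = pair_path_indexes(kg, negatives, pc, ex))
  }
  foldp <- sample(rep_len(seq_len(k), nrow(positives)))
  foldn <- sample(rep_len(seq_len(k), nrow(negatives)))
  wpos <- if ("weight" %in% names(positives)) positives$weight
          else rep(1, nrow(positives))
  wneg <- if ("weight" %in% names(negatives)) negatives$weight
          else rep(1, nrow(negatives))
  out <- vector("list", k)
  for (f in seq_len(k)) {
    trp <- foldp != f; trn <- foldn != f
    model <- pathrules(
      kg = NULL,
      positives = cbind(positives[trp, c("gene_a", "gene_b")],
                        weight = wpos[trp]),
      negatives = cbind(negatives[trn, c("gene_a", "gene_b")],
                        weight = wneg[trn]),
      indexes = list(positive = indexes$positive[trp],
                     negative = indexes$negative[trn]), ...)
    test_idx <- c(indexes$positive[!trp], indexes$negative[!trn])
    pred <- predict(model, indexes = test_idx)
    labels <- c(rep(TRUE, sum(!trp)), rep(FALSE, sum(!trn)))
    roc <- roc_points(pred$probability, labels)
    pr <- pr_points(pred$probability, labels)
    out[[f]] <- list(
      fold = f,
      predictions = data.frame(probability = pred$probability,
                               label = labels,
                               weight = c(wpos[!trp], wneg[!trn])),
      auroc = .trapezoid(roc$fpr, roc$sensitivity),
      auprc = .trapezoid(pr$recall, pr$precision),
      roc = roc, pr = pr,
      rules = vapply(model$rules, format_rule, character(1)))
  }
  out
}

#' Vertically average fold ROC / PR curves
#'
#' Interpolates each fold's curve on a fixed 101-point grid (false positive
#' rate for ROC, recall for PR), averages point-wise, and reports the area
#' under the averaged curve together with the spread of the per-fold areas.
#'
#' @param folds output of [stratified_cv()].
#' @return list with `roc` and `pr` data.frames (`grid`, `mean`, `sd`),
#'   `auroc`, `auroc_sd`, `auprc`, `auprc_sd`.
#' @export
average_curves <- function(folds) {
  grid <- seq(0, 1, by = 0.01)
  interp <- function(x, y) {
    o <- order(x, y)
    stats::approx(x[o], y[o], xout = grid, ties = max, rule = 2)$y
  }
  roc_m <- vapply(folds, function(f)
    interp(f$roc$fpr, f$roc$sensitivity), numeric(length(grid)))
  pr_m <- vapply(folds, function(f)
    interp(f$pr$recall, f$pr$precision), numeric(length(grid)))
  roc_mean <- rowMeans(roc_m); pr_mean <- rowMeans(pr_m)
  sd0 <- function(m) apply(m, 1, stats::sd)
  list(
    roc = data.frame(grid = grid, mean = roc_mean, sd = sd0(roc_m)),
    pr = data.frame(grid = grid, mean = pr_mean, sd = sd0(pr_m)),
    auroc = .trapezoid(grid, roc_mean),
    auroc_sd = stats::sd(vapply(folds, function(f) f$auroc, numeric(1))),
    auprc = .trapezoid(grid, pr_mean),
    auprc_sd = stats::sd(vapply(folds, function(f) f$auprc, numeric(1))))
}

#' Optimal classification threshold by geometric mean
#'
#' Picks the ROC point maximizing the geometric mean of sensitivity and
#' specificity.
#'
#' @param roc data.frame from [roc_points()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `gmean`.
#' @export
optimal_threshold <- function(roc) {
  g <- sqrt(roc$sensitivity * roc$specificity)
  i <- which.max(g)
  list(threshold = roc$threshold[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], gmean = g[i])
}

#' Random walk with restart baseline score
#'
#' Degree-normalized random walk with restart on the direction-agnostic
#' graph (excluded node types removed), iterated to stationarity; the
#' score of a pair is the stationary probability of one gene when
#' restarting at the other, averaged over the two directions.
#'
#' @param kg a `knowledge_graph`.
#' @param pair character vector of two Gene URIs.
#' @param restart restart probability (default 0.7).
#' @param exclude_types node types removed from the walk.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @return a real in \[0,1\]; 0 for pairs in different components.
#' @export
rwr_score <- function(kg, pair, restart = 0.7,
                      exclude_types = c("Disease", "OligogenicCombination"),
                      tol = 1e-10) {
  keep <- !(kg$nodes$type %in% exclude_types)
  uris <- kg$nodes$uri[keep]
  id <- stats::setNames(seq_along(uris), uris)
  if (!all(pair %in% uris)) stop("pair genes not in the walk graph")
  si <- id[kg$edges$source]; ti <- id[kg$edges$target]
  ok <- !is.na(si) & !is.na(ti)
  si <- si[ok]; ti <- ti[ok]
  n <- length(uris)
  A <- Matrix::sparseMatrix(i = c(si, ti), j = c(ti, si),
                            x = 1, dims = c(n, n))
  deg <- Matrix::colSums(A)
  one_dir <- function(from, to) {
    p <- numeric(n); p[id[[from]]] <- 1
    e <- p
    repeat {
      spread <- p / pmax(deg, 1)
      spread[deg == 0] <- 0
      pn <- as.numeric(A %*% spread) * (1 - restart) + restart * e
      # walkers at degree-0 nodes restart
      pn <- pn + (1 - restart) * sum(p[deg == 0]) * e
      if (sum(abs(pn - p)) < tol) break
      p <- pn
    }
    pn[id[[to]]]
  }
  (one_dir(pair[1], pair[2]) + one_dir(pair[2], pair[1])) / 2
}

#' Metapaths associated with higher rule confidence
#'
#' For every metapath occurring as a condition in some but not all rules,
#' compares the confidence of the rules containing it against the rules
#' not containing it with a one-tailed (greater) Wilcoxon rank-sum test,
#' applies a Bonferroni correction over the tested metapaths, and reports
#' the metapaths with adjusted p-value at or below `alpha`, ranked by
#' rank-biserial correlation effect size.
#'
#' @param rules list of `kg_rule` with `confidence` set.
#' @param alpha adjusted p-value cutoff (default 0.01).
#' @return data.frame `metapath`, `n_with`, `n_without`, `p`, `adj_p`,
#'   `rank_biserial`, significant rows only, ordered by effect size; the
#'   unfiltered table is attached as attribute `"all"`.
#' @export
metapath_influence <- function(rules, alpha = 0.01) {
  if (length(rules) < 2) stop("need at least two rules")
  conf <- vapply(rules, function(r) r$confidence, numeric(1))
  mps <- sort(unique(unlist(lapply(rules, function(r) r$conditions))))
  rows <- list()
  for (mp in mps) {
    has <- vapply(rules, function(r) mp %in% r$conditions, logical(1))
    if (all(has) || !any(has)) next  # no contrast
    x <- conf[has]; y <- conf[!has]
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                              exact = FALSE))
    u <- unname(wt$statistic)
    rows[[mp]] <- data.frame(
      metapath = mp, n_with = length(x), n_without = length(y),
      p = wt$p.value, rank_biserial = 2 * u / (length(x) * length(y)) - 1,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(metapath = character(), n_with = integer(),
                      n_without = integer(), p = numeric(),
                      adj_p = numeric(), rank_biserial = numeric()))
  tab <- do.call(rbind, rows)
  tab$adj_p <- pmin(1, tab$p * nrow(tab))  # Bonferroni
  tab <- tab[, c("metapath", "n_with", "n_without", "p", "adj_p",
                 "rank_biserial")]
  tab <- tab[order(-tab$rank_biserial), ]
  rownames(tab) <- NULL
  sig <- tab[tab$adj_p <= alpha, , drop = FALSE]
  attr(sig, "all") <- tab
  sig
}

#' Connectivity ratio of gene pairs under metaedge subsets
#'
#' Fraction of gene pairs connected by at least one path of length at most
#' each cutoff, traversing only the given metaedges (direction-agnostic)
#' and avoiding the excluded node types.
#'
#' @param kg a `knowledge_graph`.
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param metaedges metaedge abbreviations to retain (default all).
#' @param cutoffs path length cutoffs (default 1:4).
#' @param exclude_types node types never traversed.
#' @return data.frame `cutoff`, `n_connected`, `ratio`.
#' @export
connectivity_ratio <- function(kg, pairs, metaedges = NULL, cutoffs = 1:4,
                               exclude_types = c("Disease",
                                                 "OligogenicCombination")) {
  if (is.null(metaedges)) metaedges <- unique(kg$edges$metaedge)
  keep_e <- kg$edges$metaedge %in% metaedges
  id <- kg$index$uri_id
  excluded <- kg$nodes$type %in% exclude_types
  n <- nrow(kg$nodes)
  si <- id[kg$edges$source[keep_e]]; ti <- id[kg$edges$target[keep_e]]
  adj <- split(c(ti, si), factor(c(si, ti), levels = seq_len(n)))
  maxc <- max(cutoffs)
  dist_within <- function(a, b) {
    # BFS from a, up to maxc hops, intermediates not excluded
    if (is.na(a) || is.na(b)) return(Inf)
    dist <- rep(Inf, n); dist[a] <- 0
    frontier <- a
    d <- 0
    while (length(frontier) && d < maxc) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.finite(nxt)]
      nxt <- nxt[dist[nxt] > d]
      if (!length(nxt)) break
      dist[nxt] <- d
      if (is.finite(dist[b])) break
      frontier <- nxt[!excluded[nxt]]
    }
    dist[b]
  }
  dists <- vapply(seq_len(nrow(pairs)), function(i)
    dist_within(id[[pairs$gene_a[i]]], id[[pairs$gene_b[i]]]), numeric(1))
  data.frame(cutoff = cutoffs,
             n_connected = vapply(cutoffs, function(cc)
               sum(dists <= cc), integer(1)),
             ratio = vapply(cutoffs, function(cc)
               mean(dists <= cc), numeric(1)))
}
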