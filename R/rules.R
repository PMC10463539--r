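#' Create a metapath association rule
#'
#' A rule is a conjunction of metapath conditions, each with a path
#' reliability threshold, optionally constrained by a single unification
#' (two conditions must be satisfiable by paths sharing the same node at
#' stated intermediate positions). A gene pair matches the rule when every
#' condition has at least one path of that metapath with reliability at or
#' above its threshold, consistent with the unification if present.
#'
#' @param conditions character vector of metapath abbreviations (stored
#'   sorted; at most one occurrence each).
#' @param thresholds numeric vector of per-condition reliability thresholds
#'   in \[0,1\] (default all 0). Follows the sorted condition order.
#' @param unification `NULL`, or a list with `cond_i`, `pos_i`, `cond_j`,
#'   `pos_j` (condition indices in sorted order and 1-based node positions
#'   within the path; positions must be intermediate) and `type` (the shared
#'   node type).
#' @param support,confidence,probability optional cached statistics.
#' @return an object of class `kg_rule`.
#' @export
new_rule <- function(conditions, thresholds = NULL, unification = NULL,
                     support = NA_real_, confidence = NA_real_,
                     probability = NA_real_) {
  if (anyDuplicated(conditions)) stop("duplicate condition metapaths")
  ord <- order(conditions)
  if (is.null(thresholds)) thresholds <- rep(0, length(conditions))
  stopifnot(length(thresholds) == length(conditions),
            all(thresholds >= 0 & thresholds <= 1))
  conditions_s <- conditions[ord]
  thresholds_s <- thresholds[ord]
  if (!is.null(unification)) {
    # re-index unification onto the sorted condition order
    remap <- match(seq_along(conditions), ord)
    unification$cond_i <- remap[unification$cond_i]
    unification$cond_j <- remap[unification$cond_j]
    pi <- parse_metapath(conditions_s[unification$cond_i])
    pj <- parse_metapath(conditions_s[unification$cond_j])
    if (unification$pos_i <= 1 || unification$pos_i >= length(pi$types) ||
        unification$pos_j <= 1 || unification$pos_j >= length(pj$types))
      stop("unification positions must be intermediate")
    ti <- pi$types[unification$pos_i]; tj <- pj$types[unification$pos_j]
    if (!identical(ti, tj)) stop("unification joins different node types: ",
                                 ti, " vs ", tj)
    unification$type <- ti
    if (unification$cond_i == unification$cond_j)
      stop("unification must span two distinct conditions")
  }
  structure(list(conditions = conditions_s, thresholds = thresholds_s,
                 unification = unification, support = support,
                 confidence = confidence, probability = probability),
            class = "kg_rule")
}

#' @export
print.kg_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  stats <- c(support = x$support, confidence = x$confidence,
             probability = x$probability)
  stats <- stats[!is.na(stats)]
  if (length(stats))
    cat(" ", paste(names(stats), signif(stats, 4), sep = "=",
                   collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a rule in abbreviated metapath syntax
#'
#' Conditions are joined by `&`; a unification is rendered by indexing the
#' shared node type in both metapaths (e.g. `GaBP1aG & GaBP2aGpG ;
#' BP1=BP2`); non-zero reliability thresholds are appended as `>=theta`.
#'
#' @param rule a `kg_rule`.
#' @return a single string.
#' @export
format_rule <- function(rule) {
  conds <- rule$conditions
  u <- rule$unification
  rendered <- conds
  if (!is.null(u)) {
    rendered[u$cond_i] <- .insert_index(conds[u$cond_i], u$pos_i, 1L)
    rendered[u$cond_j] <- .insert_index(conds[u$cond_j], u$pos_j, 2L)
  }
  th <- rule$thresholds
  has_th <- !is.na(th) & th > 0
  rendered[has_th] <- paste0(rendered[has_th], ">=",
                             formatC(th[has_th], digits = 3, format = "g"))
  out <- paste(rendered, collapse = " & ")
  if (!is.null(u))
    out <- paste0(out, " ; ", .node_abbrev(u$type), "1=",
                  .node_abbrev(u$type), "2")
  out
}

.insert_index <- function(abbrev, pos, index) {
  toks <- regmatches(abbrev, gregexpr("[A-Z]+|[a-z]", abbrev))[[1]]
  node_slots <- seq(1, length(toks), by = 2)
  toks[node_slots[pos]] <- paste0(toks[node_slots[pos]], index)
  paste(toks, collapse = "")
}

#' Does a gene pair match a rule?
#'
#' @param rule a `kg_rule`.
#' @param index a `gene_pair_paths` object ([enumerate_paths()]).
#' @return logical flag: `TRUE` iff every condition has at least one path at
#'   or above its threshold and, when a unification is present, some choice
#'   of qualifying paths shares the same node at the stated positions.
#' @export
rule_matches <- function(rule, index) {
  qual <- .qualifying_paths(rule, index)
  if (is.null(qual)) return(FALSE)
  if (is.null(rule$unification)) return(TRUE)
  length(.unified_nodes(rule, index, qual)) > 0
}

# per-condition qualifying path ids, or NULL if some condition fails
.qualifying_paths <- function(rule, index) {
  out <- vector("list", length(rule$conditions))
  for (c in seq_along(rule$conditions)) {
    ids <- index$by_metapath[[rule$conditions[c]]]
    if (is.null(ids)) return(NULL)
    th <- rule$thresholds[c]
    if (th > 0) {
      rel <- vapply(index$paths[ids], function(p) p$reliability, numeric(1))
      ids <- ids[rel >= th - 1e-12]
    }
    if (!length(ids)) return(NULL)
    out[[c]] <- ids
  }
  out
}

# nodes shared between the unified positions of qualifying paths
.unified_nodes <- function(rule, index, qual) {
  u <- rule$unification
  ni <- vapply(index$paths[qual[[u$cond_i]]],
               function(p) p$nodes[u$pos_i], character(1))
  nj <- vapply(index$paths[qual[[u$cond_j]]],
               function(p) p$nodes[u$pos_j], character(1))
  intersect(ni, nj)
}

#' Build mining transactions from per-pair path indexes
#'
#' Each labelled gene pair becomes one transaction: its item set is the set
#' of metapaths with at least one path, its weight the label-confidence
#' weight, and the underlying path index is retained for threshold and
#' unification evaluation.
#'
#' @param indexes list of `gene_pair_paths`.
#' @param weights numeric vector of instance weights in (0,1\].
#' @param ids optional identifiers (default `source_target`).
#' @return an object of class `pr_transactions`.
#' @export
build_transactions <- function(indexes, weights = NULL, ids = NULL) {
  n <- length(indexes)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (is.null(ids))
    ids <- vapply(indexes, function(x) paste(x$source, x$target, sep = "_"),
                  character(1))
  items <- lapply(indexes, function(x) sort(names(x$by_metapath)))
  structure(list(items = items, weights = weights, indexes = indexes,
                 ids = ids), class = "pr_transactions")
}

#' @export
print.pr_transactions <- function(x, ...) {
  cat("Transactions:", length(x$items), "gene pairs, total weight",
      signif(sum(x$weights), 5), "\n")
  invisible(x)
}

#' Weighted Apriori mining of frequent metapath itemsets
#'
#' Level-wise search over metapath itemsets in the positive transactions.
#' The support of an itemset is the weight of the transactions containing
#' all of its items divided by the total weight; itemsets of up to
#' `max_rule_length` items with support at or above `minsup_ratio` are
#' returned. Support is anti-monotone, which the level-wise candidate
#' generation exploits.
#'
#' @param transactions a `pr_transactions` object.
#' @param minsup_ratio minimum weighted relative support (default 0.2).
#' @param max_rule_length maximum itemset size (default 3).
#' @return list of frequent itemsets, each `list(items, support)`, in
#'   lexicographic order of the item vectors.
#' @export
apriori_mine <- function(transactions, minsup_ratio = 0.2,
                         max_rule_length = 3) {
  if (!length(transactions$items)) stop("empty transaction set")
  stopifnot(minsup_ratio > 0, minsup_ratio <= 1)
  w <- transactions$weights
  W <- sum(w)
  universe <- sort(unique(unlist(transactions$items)))
  if (!length(universe)) return(list())
  M <- vapply(universe, function(it)
    vapply(transactions$items, function(s) it %in% s, logical(1)),
    logical(length(transactions$items)))
  M <- matrix(M, nrow = length(transactions$items))
  colnames(M) <- universe
  supp1 <- colSums(M * w) / W
  frequent <- list()
  Lk <- lapply(which(supp1 >= minsup_ratio - 1e-12), function(j) universe[j])
  for (s in Lk) frequent[[length(frequent) + 1L]] <-
    list(items = s, support = supp1[[s]])
  k <- 1L
  while (length(Lk) >= 2 && k < max_rule_length) {
    k <- k + 1L
    keys <- vapply(Lk, paste, character(1), collapse = "\r")
    cand <- list()
    for (a in seq_along(Lk)) for (b in seq_along(Lk)) {
      if (a >= b) next
      ia <- Lk[[a]]; ib <- Lk[[b]]
      if (k > 2 && !identical(ia[-(k - 1L)], ib[-(k - 1L)])) next
      un <- sort(unique(c(ia, ib)))
      if (length(un) != k) next
      # prune: all (k-1)-subsets must be frequent
      ok <- all(vapply(seq_len(k), function(d)
        paste(un[-d], collapse = "\r") %in% keys, logical(1)))
      if (ok) cand[[paste(un, collapse = "\r")]] <- un
    }
    Lk <- list()
    for (un in cand) {
      cover <- rowSums(M[, un, drop = FALSE]) == length(un)
      s <- sum(w[cover]) / W
      if (s >= minsup_ratio - 1e-12) {
        Lk[[length(Lk) + 1L]] <- un
        frequent[[length(frequent) + 1L]] <- list(items = un, support = s)
      }
    }
  }
  ord <- order(vapply(frequent, function(f) paste(f$items, collapse = "\r"),
                      character(1)))
  frequent[ord]
}

#' Extend frequent itemsets with unification constraints
#'
#' For every itemset of at least two metapaths, every pair of intermediate
#' positions across two distinct conditions with equal node type is a
#' unification candidate; the unified rule is kept when its weighted support
#' (fraction of transactions matching under the shared-node constraint)
#' still meets `minsup_ratio`. Unified patterns carry exactly one
#' unification.
#'
#' @param itemsets output of [apriori_mine()].
#' @param transactions a `pr_transactions`.
#' @param minsup_ratio minimum weighted support.
#' @return list of unified `kg_rule` objects.
#' @export
extend_with_unifications <- function(itemsets, transactions,
                                     minsup_ratio = 0.2) {
  w <- transactions$weights
  W <- sum(w)
  out <- list()
  for (f in itemsets) {
    if (length(f$items) < 2) next
    items <- f$items  # already sorted
    parsed <- lapply(items, parse_metapath)
    has_items <- vapply(transactions$items, function(s)
      all(items %in% s), logical(1))
    for (a in seq_along(items)) for (b in seq_along(items)) {
      if (a >= b) next
      ta <- parsed[[a]]$types; tb <- parsed[[b]]$types
      for (pa in seq_along(ta)[-c(1, length(ta))])
        for (pb in seq_along(tb)[-c(1, length(tb))]) {
          if (ta[pa] != tb[pb]) next
          rule <- new_rule(items, unification = list(
            cond_i = a, pos_i = pa, cond_j = b, pos_j = pb))
          m <- has_items
          for (i in which(has_items))
            m[i] <- rule_matches(rule, transactions$indexes[[i]])
          s <- sum(w[m]) / W
          if (s >= minsup_ratio - 1e-12) {
            rule$support <- s
            out[[length(out) + 1L]] <- rule
          }
        }
    }
  }
  out
}

#' Keep only closed patterns
#'
#' A pattern is discarded when a strictly more specific mined pattern (a
#' superset of its conditions, or the same conditions with a unification
#' added) has the same support.
#'
#' @param rules list of `kg_rule` with `support` set.
#' @param tol numeric tolerance on support equality.
#' @return the closed subset of `rules`.
#' @export
closed_only <- function(rules, tol = 1e-9) {
  n <- length(rules)
  if (n < 2) return(rules)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ri <- rules[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      rj <- rules[[j]]
      if (!all(ri$conditions %in% rj$conditions)) next
      more_specific <-
        length(rj$conditions) > length(ri$conditions) ||
        (is.null(ri$unification) && !is.null(rj$unification))
      if (!is.null(ri$unification)) {
        same_u <- !is.null(rj$unification) &&
          identical(rj$conditions[rj$unification$cond_i],
                    ri$conditions[ri$unification$cond_i]) &&
          identical(rj$conditions[rj$unification$cond_j],
                    ri$conditions[ri$unification$cond_j]) &&
          rj$unification$pos_i == ri$unification$pos_i &&
          rj$unification$pos_j == ri$unification$pos_j
        if (!same_u) next
        more_specific <- length(rj$conditions) > length(ri$conditions)
      }
      if (more_specific && abs(rj$support - ri$support) <= tol) {
        keep[i] <- FALSE
        break
      }
    }
  }
  rules[keep]
}

# weighted coverage of a rule over a transaction set (logical vector)
.rule_coverage <- function(rule, transactions) {
  conds <- rule$conditions
  quick <- vapply(transactions$items, function(s) all(conds %in% s),
                  logical(1))
  plain <- is.null(rule$unification) && all(rule$thresholds == 0)
  if (plain) return(quick)
  out <- quick
  for (i in which(quick))
    out[i] <- rule_matches(rule, transactions$indexes[[i]])
  out
}

#' Imbalance-corrected rule confidence
#'
#' The likelihood that a gene pair is pathogenic given that it satisfies the
#' rule: weighted coverage of the positive set divided by the positive
#' coverage plus the negative coverage rescaled by the class imbalance
#' `|D|/|N|` (all quantities are sums of instance weights).
#'
#' @param rule a `kg_rule`.
#' @param positives,negatives `pr_transactions` for the disease-causing (D)
#'   and neutral (N) sets.
#' @return a real in \[0,1\].
#' @export
rule_confidence <- function(rule, positives, negatives) {
  cd <- sum(positives$weights[.rule_coverage(rule, positives)])
  cn <- sum(negatives$weights[.rule_coverage(rule, negatives)])
  if (cd + cn == 0) stop("rule covers no instance; confidence undefined")
  ratio <- sum(positives$weights) / sum(negatives$weights)
  cd / (cd + ratio * cn)
}

#' Mine class association rules from positive gene pairs
#'
#' Full mining stage: weighted Apriori over metapath itemsets, extension
#' with unification constraints, and closed-pattern filtering. Each
#' resulting pattern is a candidate rule predicting the disease-causing
#' class.
#'
#' @inheritParams apriori_mine
#' @param unify search for unification constraints (default `TRUE`).
#' @return list of `kg_rule` objects with supports, in deterministic order.
#' @export
mine_rules <- function(transactions, minsup_ratio = 0.2,
                       max_rule_length = 3, unify = TRUE) {
  itemsets <- apriori_mine(transactions, minsup_ratio, max_rule_length)
  rules <- lapply(itemsets, function(f)
    new_rule(f$items, support = f$support))
  if (unify)
    rules <- c(rules, extend_with_unifications(itemsets, transactions,
                                               minsup_ratio))
  rules <- closed_only(rules)
  ord <- order(vapply(rules, format_rule, character(1)))
  rules[ord]
}
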