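#' Weighted set-cover objective of a rule collection
#'
#' The weight of a candidate decision set balances missed positive coverage
#' against incurred negative coverage:
#' `alpha * (1 - |C_R(D)|/|D|) + (1 - alpha) * |C_R(N)|/|N|`, where
#' coverages and set sizes are sums of instance weights and `C_R` is the
#' union of the member rules' coverages. An empty collection has weight
#' `alpha`; a collection covering all of D and none of N has weight 0.
#'
#' @param rules list of `kg_rule` (may be empty).
#' @param positives,negatives `pr_transactions` for D and N.
#' @param alpha trade-off in \[0,1\] (default 0.5).
#' @return a real in \[0,1\].
#' @export
set_weight <- function(rules, positives, negatives, alpha = 0.5) {
  if (!length(positives$items) || !length(negatives$items))
    stop("both positive and negative sets must be non-empty")
  covD <- covN <- NULL
  for (r in rules) {
    covD <- if (is.null(covD)) .rule_coverage(r, positives) else
      covD | .rule_coverage(r, positives)
    covN <- if (is.null(covN)) .rule_coverage(r, negatives) else
      covN | .rule_coverage(r, negatives)
  }
  dW <- if (is.null(covD)) 0 else sum(positives$weights[covD])
  nW <- if (is.null(covN)) 0 else sum(negatives$weights[covN])
  alpha * (1 - dW / sum(positives$weights)) +
    (1 - alpha) * (nW / sum(negatives$weights))
}

#' Marginal weight of adding a rule to a decision set
#'
#' @param rule candidate `kg_rule`.
#' @param rules current decision set (list of `kg_rule`).
#' @inheritParams set_weight
#' @return `set_weight(rules + rule) - set_weight(rules)`; negative when the
#'   rule improves the set.
#' @export
marginal_weight <- function(rule, rules, positives, negatives, alpha = 0.5) {
  set_weight(c(rules, list(rule)), positives, negatives, alpha) -
    set_weight(rules, positives, negatives, alpha)
}

#' Imbalance-corrected class probability of a rule
#'
#' The probability estimate for the disease-causing label given a rule
#' match: `|C_r(D)| / (|C_r(D)| + (|D|/|N|) * |C_r(N)|)`, all quantities
#' weighted. Equal to the rule's precision when the classes are balanced.
#'
#' @param rule a `kg_rule`.
#' @inheritParams set_weight
#' @return a real in \[0,1\].
#' @export
rule_probability <- function(rule, positives, negatives) {
  rule_confidence(rule, positives, negatives)
}

# greedy weighted set cover over precomputed coverage matrices
# covD: n_pos x r logical; covN: n_neg x r; serial: rule serializations
.greedy_cover <- function(covD, covN, wD, wN, alpha, probs, serial) {
  WD <- sum(wD); WN <- sum(wN)
  r <- ncol(covD)
  selected <- integer()
  coveredD <- rep(FALSE, nrow(covD))
  coveredN <- rep(FALSE, nrow(covN))
  remaining <- rep(TRUE, r)
  repeat {
    cand <- which(remaining)
    if (!length(cand)) break
    marg <- vapply(cand, function(j) {
      dnew <- sum(wD[covD[, j] & !coveredD])
      nnew <- sum(wN[covN[, j] & !coveredN])
      -alpha * dnew / WD + (1 - alpha) * nnew / WN
    }, numeric(1))
    best <- min(marg)
    if (best >= 0) break
    ties <- cand[marg <= best + 1e-15]
    if (length(ties) > 1) {
      ties <- ties[order(-probs[ties], serial[ties])]
    }
    j <- ties[1]
    selected <- c(selected, j)
    coveredD <- coveredD | covD[, j]
    coveredN <- coveredN | covN[, j]
    remaining[j] <- FALSE
  }
  list(selected = selected, coveredD = coveredD, coveredN = coveredN)
}

#' Select a decision set of rules by greedy weighted set cover
#'
#' Starting from an empty set, repeatedly adds the remaining rule with the
#' most negative marginal weight and stops when no rule has a negative
#' marginal. Ties are broken by higher class probability, then by the
#' lexicographic rule serialization. The objective strictly decreases at
#' every accepted step.
#'
#' @param rules list of candidate `kg_rule`.
#' @inheritParams set_weight
#' @return the selected sub-list of `rules`, in selection order.
#' @export
greedy_select <- function(rules, positives, negatives, alpha = 0.5) {
  if (!length(rules)) stop("no candidate rules")
  covD <- vapply(rules, .rule_coverage, logical(length(positives$items)),
                 transactions = positives)
  covN <- vapply(rules, .rule_coverage, logical(length(negatives$items)),
                 transactions = negatives)
  covD <- matrix(covD, ncol = length(rules))
  covN <- matrix(covN, ncol = length(rules))
  probs <- vapply(seq_along(rules), function(j) {
    cd <- sum(positives$weights[covD[, j]])
    cn <- sum(negatives$weights[covN[, j]])
    if (cd + cn == 0) return(0)
    cd / (cd + sum(positives$weights) / sum(negatives$weights) * cn)
  }, numeric(1))
  serial <- vapply(rules, format_rule, character(1))
  sel <- .greedy_cover(covD, covN, positives$weights, negatives$weights,
                       alpha, probs, serial)
  rules[sel$selected]
}

#' Fit a path-rule decision-set classifier for gene pairs
#'
#' The full training workflow: heterogeneous paths are enumerated between
#' each labelled gene pair (anchored at the lower-RVIS gene, up to
#' `path_cutoff` edges, skipping the excluded node types), aggregated into
#' metapaths, and mined for frequent metapath patterns over the positive
#' (disease-causing) pairs with weighted Apriori, unification constraints
#' and closed-pattern filtering. Each mined rule is then refined with
#' per-condition path-reliability thresholds by differential evolution, and
#' a subset of rules is selected by greedy weighted set cover against the
#' positive and negative (neutral) sets. Selected rules carry
#' imbalance-corrected class probabilities; a pair matching several rules
#' is scored by the highest matched probability, and a pair matching none
#' is predicted neutral with a probability estimated from the uncovered
#' training instances.
#'
#' @param kg a `knowledge_graph` (may be `NULL` when `indexes` is given).
#' @param positives,negatives data.frames of labelled gene pairs with
#'   columns `gene_a`, `gene_b` and optionally `weight` (default 1).
#' @param path_cutoff maximum path length in edges (default 3).
#' @param exclude_types node types excluded from traversal (default
#'   Disease and OligogenicCombination; add `"Phenotype"` for a
#'   phenotype-free model).
#' @param minsup_ratio weighted minimum support for mining (default 0.2).
#' @param max_rule_length maximum conditions per rule (default 3).
#' @param alpha positive/negative coverage trade-off for set cover
#'   (default 0.5).
#' @param unify mine unification constraints (default `TRUE`).
#' @param optimize refine thresholds by differential evolution (default
#'   `TRUE`).
#' @param control a [de_control()] list.
#' @param seed optional integer seed controlling the optimizer.
#' @param indexes optional precomputed path indexes: a list with elements
#'   `positive` and `negative`, each a list of `gene_pair_paths` parallel
#'   to the pair tables (as returned by [pair_path_indexes()]).
#' @param verbose print progress.
#' @return an object of class `pathrules`: the selected rules with
#'   probabilities, the default negative probability, all mined rules, and
#'   the training parameters. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`.
#' @seealso [predict.pathrules()], [explain_pair()]
#' @export
pathrules <- function(kg, positives, negatives, path_cutoff = 3,
                      exclude_types = c("Disease", "OligogenicCombination"),
                      minsup_ratio = 0.2, max_rule_length = 3, alpha = 0.5,
                      unify = TRUE, optimize = TRUE, control = de_control(),
                      seed = NULL, indexes = NULL, verbose = FALSE) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  wpos <- if ("weight" %in% names(positives)) positives$weight
          else rep(1, nrow(positives))
  wneg <- if ("weight" %in% names(negatives)) negatives$weight
          else rep(1, nrow(negatives))
  if (is.null(indexes)) {
    if (verbose) message("enumerating paths for ",
                         nrow(positives) + nrow(negatives), " pairs ...")
    indexes <- list(
      positive = pair_path_indexes(kg, positives, path_cutoff, exclude_types),
      negative = pair_path_indexes(kg, negatives, path_cutoff, exclude_types))
  }
  tD <- build_transactions(indexes$positive, wpos)
  tN <- build_transactions(indexes$negative, wneg)

  if (verbose) message("mining rules ...")
  mined <- mine_rules(tD, minsup_ratio, max_rule_length, unify = unify)
  if (!length(mined)) stop("no frequent pattern at minsup_ratio = ",
                           minsup_ratio)
  if (optimize) {
    if (verbose) message("optimizing thresholds for ", length(mined),
                         " rules ...")
    mined <- lapply(mined, function(r) {
      ctx <- fitness_context(r, tD, minsup_ratio)
      optimize_thresholds(r, context = ctx, control = control)
    })
  }
  # per-rule statistics at final thresholds
  covD <- vapply(mined, .rule_coverage, logical(length(tD$items)),
                 transactions = tD)
  covN <- vapply(mined, .rule_coverage, logical(length(tN$items)),
                 transactions = tN)
  covD <- matrix(covD, ncol = length(mined))
  covN <- matrix(covN, ncol = length(mined))
  WD <- sum(tD$weights); WN <- sum(tN$weights)
  for (j in seq_along(mined)) {
    cd <- sum(tD$weights[covD[, j]]); cn <- sum(tN$weights[covN[, j]])
    mined[[j]]$support <- cd / WD
    mined[[j]]$confidence <- mined[[j]]$probability <-
      if (cd + cn > 0) cd / (cd + WD / WN * cn) else NA_real_
  }
  probs <- vapply(mined, function(r) r$probability, numeric(1))
  serial <- vapply(mined, format_rule, character(1))
  if (verbose) message("selecting decision set ...")
  sel <- .greedy_cover(covD, covN, tD$weights, tN$weights, alpha,
                       probs, serial)
  rules <- mined[sel$selected]

  # default probability for unmatched pairs, from uncovered instances
  ud <- sum(tD$weights[!sel$coveredD])
  un <- sum(tN$weights[!sel$coveredN])
  default_p <- if (ud + un > 0) ud / (ud + WD / WN * un) else 0

  structure(list(
    rules = rules, default_negative_probability = default_p,
    alpha = alpha, mined = mined,
    params = list(path_cutoff = path_cutoff, exclude_types = exclude_types,
                  minsup_ratio = minsup_ratio,
                  max_rule_length = max_rule_length, unify = unify,
                  optimize = optimize, control = control, seed = seed),
    train_sizes = c(n_positive = length(tD$items),
                    n_negative = length(tN$items)),
    call = cl), class = "pathrules")
}

#' Enumerate path indexes for a table of gene pairs
#'
#' Orders each pair by RVIS ([order_gene_pair()]) and enumerates its paths.
#'
#' @param kg a `knowledge_graph`.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @inheritParams enumerate_paths
#' @return list of `gene_pair_paths`, parallel to the rows of `pairs`.
#' @export
pair_path_indexes <- function(kg, pairs, path_cutoff = 3,
                              exclude_types = c("Disease",
                                                "OligogenicCombination")) {
  lapply(seq_len(nrow(pairs)), function(i) {
    p <- order_gene_pair(kg, pairs$gene_a[i], pairs$gene_b[i])
    enumerate_paths(kg, p, path_cutoff, exclude_types)
  })
}

#' @export
print.pathrules <- function(x, ...) {
  cat("Path-rule decision set\n")
  cat("  rules selected:", length(x$rules), "of", length(x$mined),
      "mined\n")
  cat("  alpha:", x$alpha,
      " default negative probability:",
      signif(x$default_negative_probability, 4), "\n")
  cat("  trained on", x$train_sizes[["n_positive"]], "positive /",
      x$train_sizes[["n_negative"]], "negative pairs\n")
  invisible(x)
}

#' @export
summary.pathrules <- function(object, ...) {
  df <- data.frame(
    rule = vapply(object$rules, format_rule, character(1)),
    n_conditions = vapply(object$rules, function(r) length(r$conditions),
                          integer(1)),
    unified = vapply(object$rules, function(r) !is.null(r$unification),
                     logical(1)),
    support = vapply(object$rules, function(r) r$support, numeric(1)),
    probability = vapply(object$rules, function(r) r$probability,
                         numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$probability), ]
  rownames(df) <- NULL
  structure(list(rules = df,
                 default_negative_probability =
                   object$default_negative_probability,
                 n_mined = length(object$mined)),
            class = "summary.pathrules")
}

#' @export
print.summary.pathrules <- function(x, ...) {
  cat("Selected rules (by class probability):\n")
  print(x$rules, right = FALSE)
  cat("default negative probability:",
      signif(x$default_negative_probability, 4),
      " | mined rules:", x$n_mined, "\n")
  invisible(x)
}

#' @export
coef.pathrules <- function(object, ...) {
  stats::setNames(vapply(object$rules, function(r) r$probability,
                         numeric(1)),
                  vapply(object$rules, format_rule, character(1)))
}

#' @export
plot.pathrules <- function(x, ...) {
  sup <- vapply(x$mined, function(r) r$support, numeric(1))
  pr <- vapply(x$mined, function(r) r$probability, numeric(1))
  sel <- vapply(x$mined, format_rule, character(1)) %in%
    vapply(x$rules, format_rule, character(1))
  graphics::plot(sup, pr, xlab = "rule support (weighted)",
                 ylab = "class probability",
                 pch = ifelse(sel, 19, 1),
                 col = ifelse(sel, "firebrick", "grey40"), ...)
  graphics::legend("bottomright", legend = c("selected", "mined only"),
                   pch = c(19, 1), col = c("firebrick", "grey40"),
                   bty = "n")
  invisible(x)
}

#' Predict pathogenicity of gene pairs
#'
#' Scores each pair with the highest probability among its matching rules,
#' or the model's default negative probability when no rule matches.
#'
#' @param object a fitted `pathrules` model.
#' @param kg a `knowledge_graph` (omit when `indexes` is supplied).
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param indexes optional precomputed list of `gene_pair_paths`.
#' @param ... unused.
#' @return data.frame with columns `source`, `target`, `probability`,
#'   `n_matched`, and a list column `matched` of matched rule indices
#'   (into `object$rules`) sorted by decreasing rule probability.
#' @export
predict.pathrules <- function(object, kg = NULL, pairs = NULL,
                              indexes = NULL, ...) {
  if (is.null(indexes)) {
    if (is.null(kg) || is.null(pairs))
      stop("supply either `indexes` or both `kg` and `pairs`")
    indexes <- pair_path_indexes(kg, pairs, object$params$path_cutoff,
                                 object$params$exclude_types)
  }
  n <- length(indexes)
  prob <- numeric(n); nm <- integer(n); matched <- vector("list", n)
  rp <- vapply(object$rules, function(r) r$probability, numeric(1))
  for (i in seq_len(n)) {
    hit <- which(vapply(object$rules, rule_matches, logical(1),
                        index = indexes[[i]]))
    hit <- hit[order(-rp[hit])]
    matched[[i]] <- hit
    nm[i] <- length(hit)
    prob[i] <- if (length(hit)) rp[hit[1]]
               else object$default_negative_probability
  }
  out <- data.frame(
    source = vapply(indexes, function(x) x$source, character(1)),
    target = vapply(indexes, function(x) x$target, character(1)),
    probability = prob, n_matched = nm, stringsAsFactors = FALSE)
  out$matched <- matched
  out
}

#' Serialize or load a fitted model as JSON
#'
#' @param model a `pathrules` object.
#' @param path file path.
#' @return `read_model_json()` returns a `pathrules` object (without the
#'   mined-rule table beyond the selected rules).
#' @export
write_model_json <- function(model, path) {
  ser_rule <- function(r) list(
    rule = format_rule(r), conditions = r$conditions,
    thresholds = r$thresholds,
    unification = if (is.null(r$unification)) NULL else
      r$unification[c("cond_i", "pos_i", "cond_j", "pos_j", "type")],
    support = r$support, confidence = r$confidence,
    probability = r$probability)
  obj <- list(
    model = "path-rule decision set",
    alpha = model$alpha,
    default_negative_probability = model$default_negative_probability,
    params = model$params[c("path_cutoff", "exclude_types", "minsup_ratio",
                            "max_rule_length", "unify", "optimize", "seed")],
    train_sizes = as.list(model$train_sizes),
    rules = lapply(model$rules, ser_rule))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rules <- lapply(obj$rules, function(r) {
    u <- r$unification
    if (!is.null(u)) u <- list(cond_i = u$cond_i, pos_i = u$pos_i,
                               cond_j = u$cond_j, pos_j = u$pos_j)
    new_rule(unlist(r$conditions), unlist(r$thresholds), u,
             support = r$support %||% NA_real_,
             confidence = r$confidence %||% NA_real_,
             probability = r$probability %||% NA_real_)
  })
  structure(list(
    rules = rules,
    default_negative_probability = obj$default_negative_probability,
    alpha = obj$alpha, mined = rules,
    params = lapply(obj$params, function(p)
      if (is.list(p)) unlist(p) else p),
    train_sizes = unlist(obj$train_sizes),
    call = NULL), class = "pathrules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
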