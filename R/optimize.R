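#' Precompute the fitness context of a rule
#'
#' Threshold search repeatedly re-evaluates a rule's coverage and mean path
#' count on the positive set under candidate threshold vectors. This helper
#' freezes the baseline quantities at thresholds zero (weighted coverage and
#' weighted mean number of qualifying paths) and flattens the per-pair
#' reliability vectors so that a single evaluation is a handful of
#' vectorized operations.
#'
#' @param rule a `kg_rule`.
#' @param transactions positive-set `pr_transactions`.
#' @param minsup_ratio the mining support constraint, enforced during
#'   optimization (fitness 0 below it).
#' @return an object of class `fitness_context`.
#' @export
fitness_context <- function(rule, transactions, minsup_ratio = 0.2) {
  cov0 <- .rule_coverage(rule, transactions)
  if (!any(cov0)) stop("rule covers no positive instance at zero thresholds")
  idxs <- transactions$indexes[cov0]
  w <- transactions$weights[cov0]
  m <- length(idxs)
  k <- length(rule$conditions)
  rel <- vector("list", k); pid <- vector("list", k)
  for (c in seq_len(k)) {
    rl <- lapply(idxs, .mp_reliabilities, metapath = rule$conditions[c])
    rel[[c]] <- unlist(rl, use.names = FALSE)
    pid[[c]] <- rep(seq_len(m), vapply(rl, length, integer(1)))
  }
  u <- rule$unification
  if (!is.null(u)) {
    upair <- integer(); urel_i <- numeric(); urel_j <- numeric()
    for (p in seq_len(m)) {
      index <- idxs[[p]]
      idi <- index$by_metapath[[rule$conditions[u$cond_i]]]
      idj <- index$by_metapath[[rule$conditions[u$cond_j]]]
      ni <- vapply(index$paths[idi], function(x) x$nodes[u$pos_i], character(1))
      nj <- vapply(index$paths[idj], function(x) x$nodes[u$pos_j], character(1))
      ri <- vapply(index$paths[idi], function(x) x$reliability, numeric(1))
      rj <- vapply(index$paths[idj], function(x) x$reliability, numeric(1))
      shared <- intersect(ni, nj)
      for (s in shared) {
        upair <- c(upair, p)
        urel_i <- c(urel_i, max(ri[ni == s]))
        urel_j <- c(urel_j, max(rj[nj == s]))
      }
    }
    unif <- list(pair = upair, rel_i = urel_i, rel_j = urel_j,
                 ci = u$cond_i, cj = u$cond_j)
  } else unif <- NULL

  ctx <- structure(list(rule = rule, m = m, w = w, rel = rel, pid = pid,
                        unif = unif, W_all = sum(transactions$weights),
                        minsup = minsup_ratio),
                   class = "fitness_context")
  base <- .ctx_eval(ctx, rep(0, k))
  ctx$cov0_w <- base$cov_w
  ctx$mp0 <- base$mean_paths
  ctx
}

# evaluate coverage / mean path count at a threshold vector
.ctx_eval <- function(ctx, theta) {
  m <- ctx$m
  k <- length(theta)
  cnt <- matrix(0L, m, k)
  eps <- 1e-12
  for (c in seq_len(k)) {
    keep <- ctx$rel[[c]] >= theta[c] - eps
    cnt[, c] <- tabulate(ctx$pid[[c]][keep], nbins = m)
  }
  ok <- rowSums(cnt > 0L) == k
  if (!is.null(ctx$unif)) {
    sel <- ctx$unif$rel_i >= theta[ctx$unif$ci] - eps &
      ctx$unif$rel_j >= theta[ctx$unif$cj] - eps
    uok <- logical(m)
    uok[ctx$unif$pair[sel]] <- TRUE
    ok <- ok & uok
  }
  cov_w <- sum(ctx$w[ok])
  mp <- if (cov_w > 0) sum(ctx$w[ok] * rowSums(cnt)[ok]) / cov_w else NA_real_
  list(cov_w = cov_w, mean_paths = mp, covered = ok)
}

#' Weighted mean number of qualifying paths
#'
#' Over the positive pairs still covered by the rule at thresholds `theta`,
#' the weighted mean of the number of paths satisfying every condition
#' threshold (for unified rules, individual qualifying paths are counted).
#'
#' @param rule a `kg_rule`.
#' @param theta numeric threshold vector (one per condition).
#' @param transactions positive-set `pr_transactions`.
#' @return a non-negative real; `NA` when nothing is covered.
#' @export
mean_paths <- function(rule, theta, transactions) {
  ctx <- fitness_context(rule, transactions, minsup_ratio = 0)
  .ctx_eval(ctx, theta)$mean_paths
}

#' Rule fitness under a threshold vector
#'
#' Balances retained support against path filtering: half the sum of the
#' coverage ratio (weighted coverage at `theta` over the zero-threshold
#' coverage) and one minus the mean-path-count ratio. Returns 0 whenever
#' the support at `theta` falls below the mining support constraint, so the
#' minimum-support constraint is enforced throughout the search.
#'
#' @param context a `fitness_context`.
#' @param theta numeric threshold vector in \[0,1\]^k.
#' @return the fitness value (0.5 at `theta = 0` when the baseline is
#'   feasible).
#' @export
rule_fitness <- function(context, theta) {
  ev <- .ctx_eval(context, theta)
  if (ev$cov_w / context$W_all < context$minsup - 1e-12) return(0)
  if (ev$cov_w == 0) return(0)
  0.5 * (ev$cov_w / context$cov0_w + (1 - ev$mean_paths / context$mp0))
}

#' Differential-evolution settings
#'
#' @param popsize population size (default 50).
#' @param maxgen maximum generations (default 1000).
#' @param recombination crossover constant CR (default 0.7).
#' @param dither range from which the mutation constant F is drawn uniformly
#'   each generation (default \[0.5, 1\]).
#' @param stall stop early when the best fitness has not improved by more
#'   than `tol` for this many generations (default 50).
#' @param tol improvement tolerance for the stall criterion.
#' @return a list of settings for [optimize_thresholds()].
#' @export
de_control <- function(popsize = 50, maxgen = 1000, recombination = 0.7,
                       dither = c(0.5, 1), stall = 50, tol = 1e-6) {
  stopifnot(popsize >= 4, maxgen >= 1, recombination >= 0,
            recombination <= 1, length(dither) == 2)
  list(popsize = popsize, maxgen = maxgen, recombination = recombination,
       dither = dither, stall = stall, tol = tol)
}

#' Optimize per-condition reliability thresholds (DE/best/1/bin)
#'
#' Searches the \[0,1\]^k threshold box for the vector maximizing
#' [rule_fitness()], using the DE/best/1/bin differential-evolution scheme
#' with binomial crossover and a per-generation dithered mutation constant.
#' The zero vector is injected into the initial population, so the returned
#' fitness is never below the baseline 0.5 when the rule is feasible at
#' zero thresholds.
#'
#' @param rule a `kg_rule`.
#' @param context a `fitness_context` for that rule (built if `NULL`).
#' @param transactions used to build the context when not supplied.
#' @param minsup_ratio support constraint for a freshly built context.
#' @param control a [de_control()] list.
#' @param seed optional integer seed for reproducibility.
#' @return a `kg_rule` equal to `rule` but with optimized `thresholds`;
#'   attributes `fitness` and `generations` record the search outcome.
#' @export
optimize_thresholds <- function(rule, context = NULL, transactions = NULL,
                                minsup_ratio = 0.2, control = de_control(),
                                seed = NULL) {
  if (is.null(context)) {
    if (is.null(transactions))
      stop("supply either a fitness context or the positive transactions")
    context <- fitness_context(rule, transactions, minsup_ratio)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- length(rule$conditions)
  np <- control$popsize
  pop <- matrix(stats::runif(np * d), np, d)
  pop[1, ] <- 0  # feasible incumbent
  fit <- apply(pop, 1, function(th) rule_fitness(context, th))
  best_i <- which.max(fit)
  best_f <- fit[best_i]
  stall <- 0L
  gen <- 0L
  while (gen < control$maxgen && stall < control$stall) {
    gen <- gen + 1L
    Fc <- stats::runif(1, control$dither[1], control$dither[2])
    xbest <- pop[best_i, ]
    prev_best <- best_f
    for (i in seq_len(np)) {
      rs <- sample(seq_len(np)[-i], 2L)
      v <- xbest + Fc * (pop[rs[1], ] - pop[rs[2], ])
      v <- pmin(pmax(v, 0), 1)
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < control$recombination
      cross[jrand] <- TRUE
      trial <- pop[i, ]
      trial[cross] <- v[cross]
      ft <- rule_fitness(context, trial)
      if (ft >= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ft
        if (ft > best_f) {
          best_f <- ft
          best_i <- i
        }
      }
    }
    stall <- if (best_f - prev_best > control$tol) 0L else stall + 1L
  }
  out <- rule
  out$thresholds <- as.numeric(pop[best_i, ])
  attr(out, "fitness") <- best_f
  attr(out, "generations") <- gen
  out
}
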