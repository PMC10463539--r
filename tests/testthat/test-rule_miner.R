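test_that("apriori reproduces the textbook weighted-support example", {
  tx <- fake_transactions(list("M1", "M1", c("M1", "M2"), "M2"))
  out <- apriori_mine(tx, minsup_ratio = 0.5, max_rule_length = 2)
  sup <- stats::setNames(vapply(out, function(f) f$support, numeric(1)),
                         vapply(out, function(f)
                           paste(f$items, collapse = "+"), character(1)))
  expect_equal(sup[["M1"]], 0.75)
  expect_equal(sup[["M2"]], 0.5)
  expect_false("M1+M2" %in% names(sup))  # support 0.25 < 0.5
  # non-unit weights recompute everything
  txw <- fake_transactions(list("M1", "M1", c("M1", "M2"), "M2"),
                           weights = c(1, 1, 0.2, 0.2))
  outw <- apriori_mine(txw, minsup_ratio = 0.05, max_rule_length = 2)
  supw <- stats::setNames(vapply(outw, function(f) f$support, numeric(1)),
                          vapply(outw, function(f)
                            paste(f$items, collapse = "+"), character(1)))
  expect_equal(supw[["M1"]], 2.2 / 2.4)
  expect_equal(supw[["M2"]], 0.4 / 2.4)
  expect_equal(supw[["M1+M2"]], 0.2 / 2.4)
})

test_that("a tiny minsup returns the full powerset up to the length cap", {
  tx <- fake_transactions(list(c("A", "B", "C")))
  out <- apriori_mine(tx, minsup_ratio = 1e-6, max_rule_length = 3)
  expect_equal(length(out), 7)  # 3 + 3 + 1
  out2 <- apriori_mine(tx, minsup_ratio = 1e-6, max_rule_length = 2)
  expect_equal(length(out2), 6)
})

test_that("mining equals brute-force enumeration on random weighted instances", {
  set.seed(99)
  for (rep in 1:50) {
    n_items <- sample(3:10, 1)
    n_tx <- sample(5:50, 1)
    universe <- sprintf("M%02d", seq_len(n_items))
    items <- lapply(seq_len(n_tx), function(i)
      sort(sample(universe, sample(1:n_items, 1))))
    w <- round(stats::runif(n_tx, 0.05, 1), 3)
    minsup <- stats::runif(1, 0.1, 0.5)
    got <- apriori_mine(fake_transactions(items, w), minsup, 3)
    want <- oracle_itemsets(items, w, minsup, 3)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$items, want[[k]]$items)
      expect_equal(got[[k]]$support, want[[k]]$support, tolerance = 1e-12)
    }
  }
})

test_that("support is anti-monotone and unification never increases it", {
  set.seed(3)
  sim <- small_sim()
  idx <- pair_path_indexes(sim$kg, sim$positives)
  tx <- build_transactions(idx, sim$positives$weight)
  its <- apriori_mine(tx, 0.15, 3)
  sup <- stats::setNames(vapply(its, function(f) f$support, numeric(1)),
                         vapply(its, function(f)
                           paste(f$items, collapse = "\r"), character(1)))
  for (f in its) {
    if (length(f$items) == 1) next
    for (d in seq_along(f$items)) {
      subkey <- paste(f$items[-d], collapse = "\r")
      expect_gte(sup[[subkey]], f$support - 1e-12)
    }
  }
  uni <- extend_with_unifications(its, tx, 0.0001)
  for (r in uni)
    expect_lte(r$support,
               sup[[paste(r$conditions, collapse = "\r")]] + 1e-12)
})

test_that("rule matching honours thresholds and unification constraints", {
  kg <- tiny_kg()
  idx <- enumerate_paths(kg, c("g1", "g2"), 2)
  r1 <- new_rule("GpG", thresholds = 0.5)
  expect_true(rule_matches(r1, idx))
  expect_false(rule_matches(new_rule("GpG", thresholds = 0.95), idx))
  expect_false(rule_matches(new_rule("GeG"), idx))
  # unified rule across GaBPaG and GaBPaGpG on a graph where the shared
  # BP exists only after planting
  nodes <- data.frame(
    uri = c("x1", "x2", "x3", "bpA", "bpB"),
    type = c("Gene", "Gene", "Gene", "BiologicalProcess",
             "BiologicalProcess"))
  nodes$props <- list(list(RVIS = -1), list(RVIS = 1), list(RVIS = 0),
                      NULL, NULL)
  edges <- data.frame(
    source = c("x1", "x2", "x1", "x3", "x3"),
    target = c("bpA", "bpA", "bpB", "bpB", "x2"),
    metaedge = c("GaBP", "GaBP", "GaBP", "GaBP", "GpG"),
    score = 0.9)
  kg2 <- knowledge_graph(nodes, edges)
  ru <- new_rule(c("GaBPaG", "GaBPaGpG"),
                 unification = list(cond_i = 1, pos_i = 2,
                                    cond_j = 2, pos_j = 2))
  idx2 <- enumerate_paths(kg2, c("x1", "x2"), 3)
  # bpA joins x1-x2 directly; bpB joins x1 and x3 (interactor of x2):
  # disjoint BPs, so the unified rule must not match
  expect_true(rule_matches(new_rule(c("GaBPaG", "GaBPaGpG")), idx2))
  expect_false(rule_matches(ru, idx2))
  # planting the shared BP makes it match
  kg3 <- plant_pattern(kg2, c("x1", "x2"), c("GaBPaG", "GaBPaGpG"),
                       unification = list(cond_i = 1, pos_i = 2,
                                          cond_j = 2, pos_j = 2),
                       seed = 1)
  idx3 <- enumerate_paths(kg3, c("x1", "x2"), 3)
  expect_true(rule_matches(ru, idx3))
})

test_that("unification candidates must be intermediate and span two conditions", {
  expect_error(new_rule(c("GaBPaG", "GaBPaGpG"),
                        unification = list(cond_i = 1, pos_i = 1,
                                           cond_j = 2, pos_j = 2)),
               "intermediate")
  expect_error(new_rule(c("GaBPaG", "GuPDuG"),
                        unification = list(cond_i = 1, pos_i = 2,
                                           cond_j = 2, pos_j = 2)),
               "different node types")
})

test_that("unified patterns are found when planted and absent otherwise", {
  # 4 unit-weight pairs; 3 carry the unified pattern
  base <- knowledge_graph(
    nodes = {
      nd <- data.frame(uri = sprintf("y%d", 1:8), type = "Gene")
      nd$props <- lapply(1:8, function(i) list(RVIS = i))
      nd
    })
  pairs <- list(c("y1", "y2"), c("y3", "y4"), c("y5", "y6"), c("y7", "y8"))
  kg <- base
  for (i in 1:3)
    kg <- plant_pattern(kg, pairs[[i]], c("GaMFaG", "GaMFrMFaG"),
                        unification = list(cond_i = 1, pos_i = 2,
                                           cond_j = 2, pos_j = 2),
                        seed = i)
  kg <- plant_pattern(kg, pairs[[4]], "GaMFaG", seed = 99)
  idx <- lapply(pairs, function(p) enumerate_paths(kg, p, 3))
  tx <- build_transactions(idx)
  its <- apriori_mine(tx, 0.5, 2)
  uni <- extend_with_unifications(its, tx, 0.5)
  expect_equal(length(uni), 1)
  expect_equal(uni[[1]]$support, 0.75)
  expect_equal(uni[[1]]$conditions, c("GaMFaG", "GaMFrMFaG"))
  # no unified rule when no node is shared anywhere
  kg_nou <- base
  for (i in 1:3) {
    kg_nou <- plant_pattern(kg_nou, pairs[[i]], "GaMFaG", seed = i)
    kg_nou <- plant_pattern(kg_nou, pairs[[i]], "GaMFrMFaG", seed = i + 10)
  }
  idx2 <- lapply(pairs, function(p) enumerate_paths(kg_nou, p, 3))
  tx2 <- build_transactions(idx2)
  uni2 <- extend_with_unifications(apriori_mine(tx2, 0.5, 2), tx2, 0.5)
  expect_equal(length(uni2), 0)
})

test_that("closed-pattern filtering drops equal-support subsets only", {
  r1 <- new_rule("M1", support = 0.75)
  r12 <- new_rule(c("M1", "M2"), support = 0.75)
  out <- closed_only(list(r1, r12))
  expect_equal(length(out), 1)
  expect_equal(out[[1]]$conditions, c("M1", "M2"))
  r12b <- new_rule(c("M1", "M2"), support = 0.5)
  out2 <- closed_only(list(r1, r12b))
  expect_equal(length(out2), 2)
})

test_that("closedness matches a brute-force oracle on random lattices", {
  set.seed(17)
  for (rep in 1:20) {
    universe <- sprintf("M%d", 1:4)
    n_tx <- 12
    items <- lapply(seq_len(n_tx), function(i)
      sort(sample(universe, sample(1:4, 1))))
    its <- oracle_itemsets(items, rep(1, n_tx), 1e-9, 4)
    rules <- lapply(its, function(f) new_rule(f$items, support = f$support))
    got <- vapply(closed_only(rules), function(r)
      paste(r$conditions, collapse = "+"), character(1))
    want <- vapply(its, function(f) {
      closed <- !any(vapply(its, function(g)
        length(g$items) > length(f$items) && all(f$items %in% g$items) &&
          abs(g$support - f$support) < 1e-12, logical(1)))
      if (closed) paste(f$items, collapse = "+") else NA_character_
    }, character(1))
    expect_setequal(unname(got), unname(want[!is.na(want)]))
  }
})

test_that("rule confidence follows the imbalance-corrected formula", {
  pos <- fake_transactions(list("M1", "M1", "M2"))
  neg <- fake_transactions(list("M1", "M3", "M3", "M3"))
  expect_equal(rule_confidence(new_rule("M2"), pos, neg), 1)
  expect_equal(rule_confidence(new_rule("M3"), pos, neg), 0)
  # weighted: CD = 1.5 of WD=2.5; CN = 0.4 of WN=1.9
  posw <- fake_transactions(list("M1", "M1", "M2"), weights = c(1, 0.5, 1))
  negw <- fake_transactions(list("M1", "M3", "M3", "M3"),
                            weights = c(0.4, 0.5, 0.5, 0.5))
  expect_equal(rule_confidence(new_rule("M1"), posw, negw),
               1.5 / (1.5 + (2.5 / 1.9) * 0.4))
  expect_error(rule_confidence(new_rule("M9"), pos, neg), "undefined")
})
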