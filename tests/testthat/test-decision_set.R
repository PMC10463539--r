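test_that("set weight hits its analytic boundary values", {
  pos <- fake_transactions(list("M1", "M1"))
  neg <- fake_transactions(list("M2", "M2"))
  expect_equal(set_weight(list(new_rule("M1")), pos, neg), 0)
  expect_equal(set_weight(list(), pos, neg, alpha = 0.5), 0.5)
  expect_equal(set_weight(list(), pos, neg, alpha = 0.3), 0.3)
  # half of D (by weight) and half of N covered -> 0.5 at alpha 0.5
  posw <- fake_transactions(list("M1", "M3"), weights = c(1, 1))
  negw <- fake_transactions(list("M1", "M4"), weights = c(1, 1))
  expect_equal(set_weight(list(new_rule("M1")), posw, negw), 0.5)
  expect_error(set_weight(list(), fake_transactions(list()), neg), "empty")
})

test_that("marginal weight is the set-weight difference", {
  pos <- fake_transactions(list("M1", "M2", "M3"))
  neg <- fake_transactions(list("M4", "M4", "M1"))
  r1 <- new_rule("M1"); r2 <- new_rule("M2")
  expect_equal(marginal_weight(r1, list(r1), pos, neg), 0)
  # adding pure positive coverage decreases the weight
  expect_lt(marginal_weight(r2, list(), pos, neg), 0)
  # agreement with direct recomputation on a 3-rule instance
  rules <- list(r1, r2, new_rule("M4"))
  for (r in rules)
    expect_equal(marginal_weight(r, rules[1:2], pos, neg),
                 set_weight(c(rules[1:2], list(r)), pos, neg) -
                   set_weight(rules[1:2], pos, neg))
})

test_that("greedy selection covers D, skips duplicates, stops at marginal >= 0", {
  pos <- fake_transactions(list("M1", "M1", "M1"))
  neg <- fake_transactions(list("M2", "M2"))
  sel <- greedy_select(list(new_rule("M1")), pos, neg)
  expect_equal(length(sel), 1)
  # identical rules: second adds marginal 0
  sel2 <- greedy_select(list(new_rule("M1"), new_rule("M1")), pos, neg)
  expect_equal(length(sel2), 1)
  # a rule covering only negatives is never selected
  sel3 <- greedy_select(list(new_rule("M1"), new_rule("M2")), pos, neg)
  expect_equal(vapply(sel3, format_rule, character(1)), "M1")
})

test_that("greedy selection reproduces an independent greedy trace", {
  set.seed(23)
  for (rep in 1:10) {
    universe <- sprintf("M%d", 1:5)
    pos <- fake_transactions(lapply(1:8, function(i)
      sort(sample(universe, sample(1:3, 1)))),
      weights = round(stats::runif(8, 0.2, 1), 2))
    neg <- fake_transactions(lapply(1:12, function(i)
      sort(sample(universe, sample(1:3, 1)))),
      weights = round(stats::runif(12, 0.2, 1), 2))
    rules <- lapply(universe, new_rule)
    got <- vapply(greedy_select(rules, pos, neg), format_rule, character(1))
    # oracle: literal greedy over marginal_weight with the documented
    # tie-break (higher probability, then lexicographic serialization)
    remaining <- rules; chosen <- list(); trace <- character()
    repeat {
      if (!length(remaining)) break
      marg <- vapply(remaining, marginal_weight, numeric(1),
                     rules = chosen, positives = pos, negatives = neg)
      if (min(marg) >= 0) break
      ties <- which(marg <= min(marg) + 1e-15)
      if (length(ties) > 1) {
        pr <- vapply(remaining[ties], function(r)
          tryCatch(rule_probability(r, pos, neg), error = function(e) 0),
          numeric(1))
        ser <- vapply(remaining[ties], format_rule, character(1))
        ties <- ties[order(-pr, ser)]
      }
      j <- ties[1]
      chosen <- c(chosen, remaining[j])
      trace <- c(trace, format_rule(remaining[[j]]))
      remaining <- remaining[-j]
    }
    expect_identical(got, trace)
  }
})

test_that("rule probability implements the imbalance correction", {
  # |D|=100, |N|=10000, |C_r(D)|=20, |C_r(N)|=200 (unit weights)
  pos <- fake_transactions(c(rep(list("M1"), 20), rep(list("Mx"), 80)))
  neg <- fake_transactions(c(rep(list("M1"), 200), rep(list("My"), 9800)))
  expect_equal(rule_probability(new_rule("M1"), pos, neg),
               20 / (20 + (100 / 10000) * 200))
  expect_equal(rule_probability(new_rule("Mx"), pos, neg), 1)
  expect_equal(rule_probability(new_rule("My"), pos, neg), 0)
  # equal-size unit-weight classes: plain precision
  pos2 <- fake_transactions(list("M1", "M2"))
  neg2 <- fake_transactions(list("M1", "M3"))
  expect_equal(rule_probability(new_rule("M1"), pos2, neg2), 0.5)
})

test_that("prediction takes the maximum matched probability or the default", {
  sim <- small_sim()
  idx <- list(positive = pair_path_indexes(sim$kg, sim$positives),
              negative = pair_path_indexes(sim$kg, sim$negatives))
  fit <- pathrules(NULL, sim$positives, sim$negatives, indexes = idx,
                   optimize = FALSE, seed = 1)
  pred <- predict(fit, indexes = c(idx$positive, idx$negative))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  rp <- vapply(fit$rules, function(r) r$probability, numeric(1))
  for (i in sample(nrow(pred), 25)) {
    index <- c(idx$positive, idx$negative)[[i]]
    hits <- which(vapply(fit$rules, rule_matches, logical(1), index = index))
    if (length(hits)) {
      expect_equal(pred$probability[i], max(rp[hits]))
      expect_equal(sort(pred$matched[[i]]), sort(hits))
      # returned in decreasing probability order
      expect_true(!is.unsorted(-rp[pred$matched[[i]]]))
    } else {
      expect_equal(pred$probability[i], fit$default_negative_probability)
    }
  }
  # deterministic
  pred2 <- predict(fit, indexes = c(idx$positive, idx$negative))
  expect_identical(pred, pred2)
})

test_that("the set-cover objective strictly decreases along the greedy trace", {
  sim <- small_sim()
  idx <- list(positive = pair_path_indexes(sim$kg, sim$positives),
              negative = pair_path_indexes(sim$kg, sim$negatives))
  tD <- build_transactions(idx$positive, sim$positives$weight)
  tN <- build_transactions(idx$negative, sim$negatives$weight)
  mined <- mine_rules(tD, 0.2, 3)
  sel <- greedy_select(mined, tD, tN)
  w <- vapply(seq(0, length(sel)), function(k)
    set_weight(sel[seq_len(k)], tD, tN), numeric(1))
  expect_true(all(diff(w) < 0))
  # after selection, every remaining rule has marginal >= 0
  rest <- mined[!(vapply(mined, format_rule, character(1)) %in%
                    vapply(sel, format_rule, character(1)))]
  for (r in rest[seq_len(min(5, length(rest)))])
    expect_gte(marginal_weight(r, sel, tD, tN), 0)
})

test_that("models serialize to JSON and reload with identical predictions", {
  sim <- small_sim()
  idx <- list(positive = pair_path_indexes(sim$kg, sim$positives),
              negative = pair_path_indexes(sim$kg, sim$negatives))
  fit <- pathrules(NULL, sim$positives, sim$negatives, indexes = idx,
                   seed = 5)
  f <- tempfile(fileext = ".json")
  write_model_json(fit, f)
  fit2 <- read_model_json(f)
  expect_equal(vapply(fit2$rules, format_rule, character(1)),
               vapply(fit$rules, format_rule, character(1)))
  expect_equal(fit2$default_negative_probability,
               fit$default_negative_probability)
  p1 <- predict(fit, indexes = idx$positive[1:10])
  p2 <- predict(fit2, indexes = idx$positive[1:10])
  expect_equal(p1$probability, p2$probability)
})
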