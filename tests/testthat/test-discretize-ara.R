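test_that("a clean class split yields a cut at the boundary", {
  vals <- c(1:9, 11:20)
  d <- make_ctg(19, ASTV = vals, NSP = as.integer(ifelse(vals < 10, 1, 3)))
  bins <- fit_class_distribution_bins(d, "ASTV")
  expect_equal(bins$edges, c(1, 11, 20))
  # both bins pure
  b1 <- rule_support_confidence(list(rule_condition("ASTV", 1, 11)), 1, d)
  b2 <- rule_support_confidence(
    list(rule_condition("ASTV", 11, 20, TRUE)), 3, d)
  expect_equal(b1$confidence, 1)
  expect_equal(b2$confidence, 1)
})

test_that("a constant feature yields a single-bin scheme", {
  d <- make_ctg(10, NSP = rep(c(1L, 3L), 5))
  bins <- fit_class_distribution_bins(d, "ASTV")
  expect_equal(length(bins$edges), 2)
  expect_equal(bins$edges[1], bins$edges[2])
})

test_that("greedy merging follows the L1-similarity order", {
  # 20 records, majority class switches at 6, 11 and 16:
  # initial bins [1,6) [6,11) [11,16) [16,20] with proportion vectors
  # (1,0,0) (0,1,0) (1,0,0) (0,0,1); all adjacent L1 distances are 2, so
  # the tie-break merges the first pair, leaving cuts at 11 and 16
  d <- make_ctg(20, ASTV = 1:20,
                NSP = as.integer(rep(c(1, 2, 1, 3), each = 5)))
  bins <- fit_class_distribution_bins(d, "ASTV", max_bins = 3,
                                      min_frac = 0.05)
  expect_equal(bins$edges, c(1, 11, 16, 20))
})

test_that("every bin respects the minimum-mass constraint", {
  d <- random_ctg(200, seed = 4, pool = 0:30)
  bins <- fit_class_distribution_bins(d, "LB", max_bins = 5, min_frac = 0.1)
  bin <- findInterval(d$data$LB, bins$edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > length(bins$edges) - 1] <- length(bins$edges) - 1
  expect_true(all(tabulate(bin) / 200 >= 0.1 - 1e-12))
  expect_lte(length(bins$edges) - 1, 5)
})

test_that("support and confidence count correctly on a fixture", {
  d <- make_ctg(10, ASTV = c(85, 90, 95, 99, 10, 20, 30, 40, 50, 60),
                NSP = c(3L, 3L, 3L, 1L, 1L, 1L, 1L, 2L, 2L, 1L))
  sc <- rule_support_confidence(
    list(rule_condition("ASTV", 80, 100, TRUE)), 3, d)
  expect_equal(sc$support, 0.4)
  expect_equal(sc$confidence, 0.75)
  expect_equal(sc$match_count, 4L)

  # pure dataset, antecedent matching everything
  d2 <- make_ctg(4, NSP = 1L)
  sc2 <- rule_support_confidence(
    list(rule_condition("ASTV", 0, 100, TRUE)), 1, d2)
  expect_equal(sc2$support, 1)
  expect_equal(sc2$confidence, 1)

  # empty antecedent: support 1, confidence = class prior
  sc3 <- rule_support_confidence(list(), 3, d)
  expect_equal(sc3$support, 1)
  expect_equal(sc3$confidence, 0.3)

  # zero matches: flagged, not NaN
  sc4 <- rule_support_confidence(
    list(rule_condition("ASTV", 200, 300)), 3, d)
  expect_false(sc4$confidence_defined)
  expect_true(is.na(sc4$confidence))
})

test_that("a perfectly separating feature gives a one-step rule", {
  vals <- c(1:12, 81:88)
  d <- make_ctg(20, ASTV = vals, NSP = as.integer(ifelse(vals > 80, 3, 1)))
  bins <- list(ASTV = fit_class_distribution_bins(d, "ASTV"))
  res <- forward_stepwise_rule(d, bins, 3, min_support = 5)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$rule$confidence, 1)
  expect_equal(attr(res$trace, "stopping_reason"), "confidence_1")
})

test_that("trace confidence is non-decreasing and support non-increasing", {
  for (seed in 1:25) {
    d <- random_ctg(n = 150, seed = 300 + seed, pool = 0:7)
    feats <- c("LB", "ASTV", "MSTV", "ALTV", "Width", "Min")
    bins <- lapply(feats, function(f)
      fit_class_distribution_bins(d, f, max_bins = 4, min_frac = 0.05))
    names(bins) <- feats
    for (k in unique(d$data$NSP)) {
      res <- forward_stepwise_rule(d, bins, k, min_support = 5)
      tr <- res$trace
      if (nrow(tr) >= 2) {
        expect_true(all(diff(tr$confidence) >= -1e-12))
        expect_true(all(diff(tr$support) <= 1e-12))
      }
      expect_gte(res$rule$match_count, 5)
      expect_true(attr(tr, "stopping_reason") %in%
                    c("confidence_1", "no_improvement", "support_floor",
                      "feature_exhausted"))
    }
  }
})

test_that("mining is deterministic", {
  d <- random_ctg(120, seed = 17, pool = 0:5)
  feats <- c("LB", "ASTV", "MSTV")
  bins <- lapply(feats, function(f) fit_class_distribution_bins(d, f))
  names(bins) <- feats
  r1 <- forward_stepwise_rule(d, bins, 1, min_support = 5)
  r2 <- forward_stepwise_rule(d, bins, 1, min_support = 5)
  expect_identical(r1, r2)
})

test_that("the exhaustive oracle bounds the greedy miner", {
  for (seed in 1:10) {
    d <- random_ctg(n = 100, seed = 500 + seed, pool = 0:5)
    feats <- c("LB", "ASTV", "MSTV", "ALTV", "Min")
    bins <- lapply(feats, function(f)
      fit_class_distribution_bins(d, f, max_bins = 4, min_frac = 0.05))
    names(bins) <- feats
    res <- forward_stepwise_rule(d, bins, 1, min_support = 5)
    len <- max(1, length(res$rule$antecedent))
    ex <- exhaustive_best_rule(d, bins, 1, min_support = 5, max_len = len)
    if (length(res$rule$antecedent) >= 1) {
      expect_lte(res$rule$confidence, ex$confidence + 1e-12)
    }
    # max_len 1 equals the greedy first step by definition
    ex1 <- exhaustive_best_rule(d, bins, 1, min_support = 5, max_len = 1)
    if (nrow(res$trace) >= 1) {
      expect_equal(ex1$confidence, res$trace$confidence[1])
    }
  }
})

test_that("the enumeration guard refuses oversized searches", {
  d <- random_ctg(50, seed = 2)
  feats <- c("LB", "ASTV", "MSTV", "ALTV", "Min", "Width")
  bins <- lapply(feats, function(f)
    fit_class_distribution_bins(d, f, max_bins = 6, min_frac = 0.02))
  names(bins) <- feats
  expect_error(
    exhaustive_best_rule(d, bins, 1, max_len = 6, guard = 10),
    "guard")
})

test_that("an absent target class raises a domain error", {
  d <- make_ctg(10, NSP = 1L)
  bins <- list(ASTV = fit_class_distribution_bins(d, "ASTV"))
  expect_error(forward_stepwise_rule(d, bins, 3), "absent")
  expect_error(exhaustive_best_rule(d, bins, 3), "absent")
})

test_that("planted conjunctive rules are recovered by both miners", {
  for (seed in c(61, 62, 63)) {
    tb <- planted_testbed(seed)
    d <- generate_dataset(tb$config)
    bins <- all_feature_bins(d)
    # the exhaustive search recovers feature set and snapped intervals:
    # maximal support among confidence-1 antecedents takes the widest
    # bin union covering the planted region
    ex <- exhaustive_best_rule(d, bins, tb$target, min_support = 5,
                               max_len = 2)
    got <- sort(vapply(ex$antecedent, `[[`, character(1), "feature"))
    expect_equal(got, tb$features)
    expect_equal(ex$confidence, 1)
    in_region <- tb$in_region(d)
    cover <- sum(rule_matches(ex$antecedent, d) & in_region) /
      sum(in_region)
    expect_gte(cover, 0.9)
    # the greedy miner reaches the same (maximal) confidence
    gr <- forward_stepwise_rule(d, bins, tb$target, min_support = 5)
    expect_equal(gr$rule$confidence, 1)
  }
})
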