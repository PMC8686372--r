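test_that("Spearman rho matches the textbook cases", {
  d <- make_ctg(3, LB = c(1, 2, 3), ASTV = c(2, 4, 6), MSTV = c(3, 2, 1))
  corr <- spearman_matrix(d)
  expect_equal(corr$rho["LB", "ASTV"], 1)
  expect_equal(corr$rho["LB", "MSTV"], -1)

  # sum d^2 = 4 over n = 5: rho = 1 - 6*4/(5*24) = 0.8
  d2 <- make_ctg(5, LB = c(1, 2, 3, 4, 5), ASTV = c(2, 1, 4, 3, 5))
  corr2 <- spearman_matrix(d2)
  expect_equal(corr2$rho["LB", "ASTV"], 0.8)
})

test_that("Spearman matrix equals the rank-then-Pearson oracle with ties", {
  for (seed in 1:50) {
    d <- random_ctg(n = sample(5:50, 1), seed = seed)
    corr <- spearman_matrix(d)
    vars <- sample(corr$variables, 4)
    for (i in 1:3) {
      for (j in (i + 1):4) {
        o <- oracle_spearman(d$data[[vars[i]]], d$data[[vars[j]]])
        got <- corr$rho[vars[i], vars[j]]
        if (is.na(o)) expect_true(is.na(got)) else
          expect_equal(got, o, tolerance = 1e-12)
      }
    }
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  maps <- list(function(x) exp(x / 3), function(x) x^3,
               function(x) -1 / (1 + exp(-x)), function(x) 5 * x - 100)
  for (seed in 1:10) {
    d <- random_ctg(30, seed = 100 + seed)
    corr <- spearman_matrix(d)
    f <- maps[[1 + seed %% length(maps)]]
    d2 <- d
    d2$data$LB <- f(d2$data$LB)
    corr2 <- spearman_matrix(d2)
    sgn <- if (f(2) > f(1)) 1 else -1
    expect_equal(corr2$rho["LB", "ASTV"], sgn * corr$rho["LB", "ASTV"],
                 tolerance = 1e-12)
  }
})

test_that("constant columns are flagged, not silently zeroed", {
  d <- random_ctg(20, seed = 5)
  d$data$DS <- 0
  corr <- spearman_matrix(d)
  expect_true(all(is.na(corr$rho["DS", ])))
  expect_true(all(corr$undefined["DS", ]))
  expect_false(any(corr$undefined["LB", setdiff(corr$variables, "DS")]))
})

test_that("correlated_groups returns the connected components above threshold", {
  # construct a correlation object with known block structure
  d <- random_ctg(40, seed = 8)
  corr <- spearman_matrix(d)
  corr$rho[] <- 0
  diag(corr$rho) <- 1
  corr$undefined[] <- FALSE
  link <- function(a, b, r) corr$rho[a, b] <<- corr$rho[b, a] <<- r
  link("LB", "Mode", 0.9); link("Mode", "Median", 0.8)
  link("Width", "Variance", -0.75)
  link("AC", "FM", 0.5)   # below threshold
  groups <- correlated_groups(corr, threshold = 0.7)
  expect_equal(groups, list(c("LB", "Mode", "Median"),
                            c("Width", "Variance")))

  # monotone: raising the threshold never merges groups
  g_low <- correlated_groups(corr, threshold = 0.4)
  expect_true(any(vapply(g_low, function(g) all(c("AC", "FM") %in% g),
                         logical(1))))
  # all-distinct data at threshold 1: no perfect correlations, no groups
  corr2 <- spearman_matrix(random_ctg(40, seed = 9, pool = 1:1000))
  expect_length(correlated_groups(corr2, threshold = 1), 0)
})

test_that("stacked proportions aggregate to class proportions in one bin", {
  d <- random_ctg(60, seed = 12)
  cc <- class_counts(d)
  bp <- stacked_proportions(d, "ASTV",
                            range(d$data$ASTV) + c(0, 1e-9))
  expect_equal(unname(bp$proportions[1, ]), unname(cc$proportions))
  expect_equal(sum(bp$count), 60)
})

test_that("stacked proportions match a hand tally on two bins", {
  d <- make_ctg(6, ASTV = c(5, 15, 25, 35, 45, 55),
                NSP = c(1L, 1L, 2L, 3L, 1L, 3L))
  bp <- stacked_proportions(d, "ASTV", c(0, 30, 60))
  expect_equal(bp$count, c(3L, 3L))
  expect_equal(unname(bp$proportions[1, ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(bp$proportions[2, ]), c(1 / 3, 0, 2 / 3))
})

test_that("refining bin edges and re-aggregating reproduces coarse bins", {
  d <- random_ctg(100, seed = 33)
  coarse <- c(0, 5, 10)
  fine <- c(0, 2, 5, 7, 10)
  bc <- stacked_proportions(d, "LB", coarse)
  bf <- stacked_proportions(d, "LB", fine)
  # bins (1,2) of fine form bin 1 of coarse; (3,4) form bin 2
  for (g in 1:2) {
    idx <- (2 * g - 1):(2 * g)
    cnt <- sum(bf$count[idx])
    expect_equal(cnt, bc$count[g])
    if (cnt > 0) {
      agg <- colSums(bf$proportions[idx, , drop = FALSE] *
                       bf$count[idx], na.rm = TRUE) / cnt
      expect_equal(unname(agg), unname(bc$proportions[g, ]))
    }
  }
})

test_that("edges not covering the range are auto-extended with a warning", {
  d <- make_ctg(4, ASTV = c(5, 20, 40, 90))
  # both the lower and the upper edge need extending
  expect_warning(expect_warning(
    bp <- stacked_proportions(d, "ASTV", c(10, 50)), "extending"),
    "extending")
  expect_equal(sum(bp$count), 4)
})
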