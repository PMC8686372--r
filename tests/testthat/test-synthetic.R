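test_that("generation is deterministic given the configuration", {
  cfg <- synth_config(1000, seed = 31)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$data, d2$data)
})

test_that("class fractions follow the configured imbalance", {
  n <- 10000
  p <- c(0.78, 0.14, 0.08)
  d <- generate_dataset(synth_config(n, class_proportions = p, seed = 7))
  cc <- class_counts(d)
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(cc$proportions - p) < 3 * se))
})

test_that("per-class means converge to the configured locations", {
  # features whose locations are neither width-linked nor truncation-biased:
  # LB and ASTV (truncated normal, location well inside the domain) and the
  # AC / UC Poisson event rates (exact means)
  n <- 20000
  cfg <- synth_config(n, seed = 13)
  d <- generate_dataset(cfg)
  prof <- cfg$profiles
  for (f in c("LB", "ASTV")) {
    row <- prof[prof$feature == f, ]
    for (k in 1:3) {
      idx <- d$data$NSP == k
      tol <- 4 * row[[paste0("s", k)]] / sqrt(sum(idx)) + 0.5  # 0.5: rounding
      expect_lt(abs(mean(d$data[[f]][idx]) - row[[paste0("m", k)]]), tol,
                label = paste(f, "class", k))
    }
  }
  for (f in c("AC", "UC")) {
    row <- prof[prof$feature == f, ]
    for (k in 1:3) {
      idx <- d$data$NSP == k
      lam <- row[[paste0("m", k)]]
      tol <- 4 * sqrt(lam / 1800) / sqrt(sum(idx))
      expect_lt(abs(mean(d$data[[f]][idx]) - lam), tol,
                label = paste(f, "class", k))
    }
  }
})

test_that("generated records satisfy the record invariants", {
  d <- generate_dataset(synth_config(5000, seed = 3))
  rep <- validate_records(d, level = "warn")
  expect_equal(nrow(rep$violations), 0)
})

test_that("planted purity-1 rules hold exactly over the whole region", {
  cfg <- synth_config(2000, seed = 11)
  r <- planted_rule(list(ASTV = c(80, 100)), target_class = 3,
                    purity = 1, region_fraction = 0.05)
  cfg2 <- plant_rule(cfg, r)
  expect_length(cfg$planted_rules, 0)   # original untouched
  d <- generate_dataset(cfg2)
  in_region <- d$data$ASTV >= 80 & d$data$ASTV <= 100
  expect_true(all(d$data$NSP[in_region] == 3L))
  expect_gte(sum(in_region), 0.05 * 2000)

  sc <- rule_support_confidence(
    list(rule_condition("ASTV", 80, 100, upper_closed = TRUE)), 3, d)
  expect_identical(sc$confidence, 1)
})

test_that("two disjoint planted rules are independently recoverable", {
  # disjoint regions of the same feature, so neither region's natural
  # values can leak into the other
  cfg <- synth_config(3000, seed = 21)
  cfg <- plant_rule(cfg, planted_rule(list(ASTV = c(85, 100)), 3,
                                      purity = 1, region_fraction = 0.06))
  cfg <- plant_rule(cfg, planted_rule(list(ASTV = c(10, 17)), 2,
                                      purity = 1, region_fraction = 0.06))
  d <- generate_dataset(cfg)
  s1 <- rule_support_confidence(
    list(rule_condition("ASTV", 85, 100, TRUE)), 3, d)
  s2 <- rule_support_confidence(
    list(rule_condition("ASTV", 10, 17, TRUE)), 2, d)
  expect_identical(s1$confidence, 1)
  expect_identical(s2$confidence, 1)
})

test_that("contradictory overlapping planted regions are rejected", {
  cfg <- synth_config(1000, seed = 1)
  cfg <- plant_rule(cfg, planted_rule(list(ASTV = c(80, 100)), 3))
  expect_error(
    plant_rule(cfg, planted_rule(list(ASTV = c(90, 99)), 1)),
    "different target class")
  # same class, overlapping: allowed
  expect_silent(plant_rule(cfg, planted_rule(list(ASTV = c(90, 99)), 3)))
})

test_that("degenerate class proportions are flagged in provenance", {
  d <- generate_dataset(synth_config(10, c(1, 0, 0), seed = 2))
  expect_match(d$provenance, "degenerate proportions")
})

test_that("synthetic configuration round-trips through YAML", {
  cfg <- synth_config(500, c(0.5, 0.3, 0.2), seed = 77,
                      planted_rules = list(
                        planted_rule(list(ASTV = c(80, 100)), 3,
                                     purity = 0.9, region_fraction = 0.1)))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, tmp)
  cfg2 <- read_synth_config(tmp)
  expect_identical(generate_dataset(cfg)$data, generate_dataset(cfg2)$data)
})

test_that("SEM samples reproduce the implied covariance", {
  model <- two_factor_model()
  mats <- two_factor_true()
  Sigma <- implied_covariance(model, mats)

  X <- generate_sem_sample(model, mats, n = 50000, seed = 5)
  S <- cov(X)
  scale <- sqrt(outer(diag(Sigma), diag(Sigma)))
  expect_lt(max(abs(S - Sigma) / scale), 5 / sqrt(50000) * 3)

  # determinism
  X2 <- generate_sem_sample(model, mats, n = 100, seed = 5)
  X3 <- generate_sem_sample(model, mats, n = 100, seed = 5)
  expect_identical(X2, X3)
})

test_that("noiseless single-factor samples have rank-1 covariance", {
  model <- build_model(list(F1 = c("v1", "v2", "v3")),
                       scaling = c(F1 = "v1"),
                       fixed_error = c(v1 = 0, v2 = 0, v3 = 0))
  Lx <- model$Lx$value; Lx[] <- c(1, 0.5, 2)
  mats <- list(Lx = Lx, Ph = matrix(2, 1, 1),
               Td = matrix(0, 3, 3))
  X <- generate_sem_sample(model, mats, n = 200, seed = 9)
  expect_equal(qr(cov(X))$rank, 1)
})
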