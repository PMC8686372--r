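# shared fixtures and independent oracles, all built in code at test time

# one internally consistent CTG record (histogram invariants hold)
.base_record <- function() {
  list(LB = 130, AC = 0.003, FM = 0.002, UC = 0.004, DL = 0.002, DS = 0,
       DP = 0, ASTV = 40, MSTV = 1.5, ALTV = 10, MLTV = 8, Width = 60,
       Min = 90, Max = 150, Nmax = 4, Nzeros = 0, Mode = 133, Mean = 132,
       Median = 134, Variance = 20, Tendency = 0, NSP = 1)
}

# small dataset: every column defaults to the base record, overridable
# with vectors recycled to n
make_ctg <- function(n, ...) {
  over <- list(...)
  base <- .base_record()
  df <- as.data.frame(lapply(base, function(v) rep(v, n)))
  for (nm in names(over)) df[[nm]] <- rep(over[[nm]], length.out = n)
  df$NSP <- as.integer(df$NSP)
  ctg_dataset(df, provenance = "test fixture")
}

# random small-integer-valued dataset (ties on purpose)
random_ctg <- function(n, seed, pool = 0:9) {
  set.seed(seed)
  base <- .base_record()
  df <- as.data.frame(lapply(base, function(v) sample(pool, n, replace = TRUE)))
  df$NSP <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  df$NSP <- as.integer(df$NSP)
  ctg_dataset(df, provenance = "random test fixture")
}

# independent mid-rank computation (comparison-count definition, not rank())
oracle_midrank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# independent Spearman rho: explicit ranking + Pearson moment formula
oracle_spearman <- function(x, y) {
  r1 <- oracle_midrank(x)
  r2 <- oracle_midrank(y)
  n <- length(x)
  num <- sum(r1 * r2) - n * mean(r1) * mean(r2)
  den <- sqrt((sum(r1^2) - n * mean(r1)^2) * (sum(r2^2) - n * mean(r2)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# planted-rule testbed: a pure two-condition suspicious-class region (A)
# guarded by pathology decoy regions that overlap each of A's intervals on
# exactly one feature, so that no single condition and no other feature pair
# can reach confidence 1, and a boundary guard below A's ALTV interval so the
# discretizer keeps the cut there
planted_testbed <- function(seed, n = 1200, region_fraction = NULL) {
  set.seed(seed)
  rf <- if (is.null(region_fraction)) runif(1, 0.05, 0.2) else region_fraction
  cfg <- synth_config(n, seed = seed)
  cfg <- plant_rule(cfg, planted_rule(
    list(MSTV = c(4.5, 6.5), ALTV = c(60, 72)), 2,
    purity = 1, region_fraction = rf))
  cfg <- plant_rule(cfg, planted_rule(
    list(MSTV = c(4.5, 6.5), ALTV = c(5, 30)), 3,
    purity = 1, region_fraction = 0.6 * rf))
  cfg <- plant_rule(cfg, planted_rule(
    list(MSTV = c(1.5, 3), ALTV = c(60, 72)), 3,
    purity = 1, region_fraction = 0.6 * rf))
  cfg <- plant_rule(cfg, planted_rule(
    list(MSTV = c(1.5, 3), ALTV = c(45, 58)), 3,
    purity = 1, region_fraction = 0.4 * rf))
  list(config = cfg, region_fraction = rf,
       target = 2L, features = c("ALTV", "MSTV"),
       in_region = function(d) {
         d$data$MSTV >= 4.5 & d$data$MSTV <= 6.5 &
           d$data$ALTV >= 60 & d$data$ALTV <= 72
       })
}

rule_matches <- function(antecedent, d) {
  keep <- rep(TRUE, nrow(d$data))
  for (cond in antecedent) {
    x <- d$data[[cond$feature]]
    keep <- keep & x >= cond$lower &
      (if (cond$upper_closed) x <= cond$upper else x < cond$upper)
  }
  keep
}

all_feature_bins <- function(d, max_bins = 6, min_frac = 0.05) {
  bins <- lapply(ctg_feature_names(), function(f)
    fit_class_distribution_bins(d, f, max_bins = max_bins,
                                min_frac = min_frac))
  names(bins) <- ctg_feature_names()
  bins
}

# small two-factor CFA model used across SEM tests
two_factor_model <- function() {
  build_model(
    latents = list(F1 = c("v1", "v2", "v3"), F2 = c("v4", "v5", "v6")),
    covariances = data.frame(a = "F1", b = "F2", stringsAsFactors = FALSE),
    scaling = c(F1 = "v1", F2 = "v4"))
}

two_factor_true <- function() {
  model <- two_factor_model()
  Lx <- model$Lx$value; Lx[] <- 0
  Lx["v1", "F1"] <- 1; Lx["v2", "F1"] <- 0.8; Lx["v3", "F1"] <- 1.2
  Lx["v4", "F2"] <- 1; Lx["v5", "F2"] <- 0.7; Lx["v6", "F2"] <- 0.9
  Ph <- matrix(c(1.5, 0.4, 0.4, 0.9), 2, 2,
               dimnames = dimnames(model$Ph$value))
  Td <- diag(c(0.5, 0.6, 0.4, 0.7, 0.5, 0.3))
  dimnames(Td) <- dimnames(model$Td$value)
  list(Lx = Lx, Ph = Ph, Td = Td)
}
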