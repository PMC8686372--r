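#' Default per-class feature profiles for the synthetic CTG generator
#'
#' One row per feature with the generating family and per-class parameters.
#' Families: `"truncnorm"` (normal truncated to `[lower, upper]`, per-class
#' mean `m1..m3` and sd `s1..s3`), `"rate"` (Poisson event count over a
#' nominal 1800 s trace divided by 1800, per-class rate in events/second in
#' `m1..m3`), `"count"` (Poisson count, per-class lambda in `m1..m3`), and
#' `"derived"` (computed from other features so that the histogram-consistency
#' invariants hold: `Max = Min + Width`; `Mode`, `Mean`, `Median` follow the
#' baseline and are clamped into `[Min, Max]`).
#'
#' The per-class locations encode the monotone per-class shifts seen in
#' clinical CTG data: pathology shifted up in `ASTV`, `ALTV`, `DP` and `LB`
#' and down in `AC` and `MSTV` relative to normal; magnitudes are
#' configurable, and correlated blocks (baseline-derived histogram statistics;
#' width/variance) induce a latent-factor covariance structure.
#'
#' @return data.frame with columns `feature`, `kind`, `m1`, `m2`, `m3`,
#'   `s1`, `s2`, `s3`, `lower`, `upper` (classes 1 = normal, 2 = suspicious,
#'   3 = pathology).
#' @export
default_class_profiles <- function() {
  p <- function(feature, kind, m, s = c(NA, NA, NA), lower = NA, upper = NA) {
    data.frame(feature = feature, kind = kind,
               m1 = m[1], m2 = m[2], m3 = m[3],
               s1 = s[1], s2 = s[2], s3 = s[3],
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  }
  rbind(
    p("LB",       "truncnorm", c(130, 137, 142),   c(9, 10, 12),   100, 180),
    p("AC",       "rate",      c(0.0040, 0.0012, 0.0004)),
    p("FM",       "rate",      c(0.0025, 0.0028, 0.0045)),
    p("UC",       "rate",      c(0.0045, 0.0032, 0.0020)),
    p("DL",       "rate",      c(0.0015, 0.0025, 0.0035)),
    p("DS",       "rate",      c(0.00002, 0.0001, 0.0006)),
    p("DP",       "rate",      c(0.0001, 0.0004, 0.0025)),
    p("ASTV",     "truncnorm", c(42, 58, 70),      c(14, 15, 18),  0, 100),
    p("MSTV",     "truncnorm", c(1.6, 0.9, 0.8),   c(0.7, 0.4, 0.5), 0, 7),
    p("ALTV",     "truncnorm", c(7, 22, 30),       c(9, 17, 22),   0, 100),
    p("MLTV",     "truncnorm", c(8.5, 7.5, 5.5),   c(5, 4, 4),     0, 50),
    p("Width",    "truncnorm", c(72, 62, 85),      c(35, 32, 45),  3, 180),
    p("Min",      "truncnorm", c(95, 100, 78),     c(25, 22, 28),  50, 150),
    p("Max",      "derived",   c(NA, NA, NA)),
    p("Nmax",     "count",     c(4, 3, 3.5)),
    p("Nzeros",   "count",     c(0.3, 0.4, 1.0)),
    p("Mode",     "derived",   c(3, 1, -6),        c(5, 5, 5)),
    p("Mean",     "derived",   c(2, 0, -8),        c(5, 5, 5)),
    p("Median",   "derived",   c(4, 2, -5),        c(5, 5, 5)),
    p("Variance", "truncnorm", c(18, 14, 55),      c(14, 12, 55),  0, 300),
    p("Tendency", "tendency",  c(NA, NA, NA))
  )
}

#' Describe a planted association-rule region
#'
#' @param conditions named list mapping feature name to `c(lower, upper)`
#'   (closed interval used for the uniform draw that places records in the
#'   region).
#' @param target_class NSP value in 1:3 forced onto region records.
#' @param purity fraction in `[0,1]` of region records given `target_class`;
#'   the remainder get one of the other two classes.
#' @param region_fraction fraction of records placed in the region,
#'   in `(0,1)`.
#' @return An object of class `ctg_planted_rule`.
#' @export
planted_rule <- function(conditions, target_class, purity = 1,
                         region_fraction = 0.05) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  for (nm in names(conditions)) {
    iv <- conditions[[nm]]
    if (length(iv) != 2 || !(iv[1] < iv[2])) {
      stop("planted_rule: interval for '", nm,
           "' must satisfy lower < upper", call. = FALSE)
    }
    if (!nm %in% ctg_feature_names()) {
      stop("planted_rule: unknown feature '", nm, "'", call. = FALSE)
    }
  }
  stopifnot(target_class %in% 1:3, purity >= 0, purity <= 1,
            region_fraction > 0, region_fraction < 1)
  structure(list(conditions = conditions,
                 target_class = as.integer(target_class),
                 purity = purity, region_fraction = region_fraction),
            class = "ctg_planted_rule")
}

#' Configuration for the synthetic CTG generator
#'
#' @param n sample size (>= 1).
#' @param class_proportions 3-vector of NSP class proportions
#'   (normal, suspicious, pathology), non-negative, summing to 1 within 1e-9.
#'   Default 0.78/0.14/0.08, the imbalance typical of antepartum screening
#'   populations.
#' @param profiles per-class feature location/scale table, see
#'   [default_class_profiles()].
#' @param planted_rules list of [planted_rule()] objects.
#' @param seed integer root seed; all stage-local substreams are derived
#'   deterministically from it.
#' @return An object of class `ctg_synth_config`.
#' @export
synth_config <- function(n, class_proportions = c(0.78, 0.14, 0.08),
                         profiles = default_class_profiles(),
                         planted_rules = list(), seed = 1L) {
  stopifnot(n >= 1, length(class_proportions) == 3,
            all(class_proportions >= 0))
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("synth_config: class_proportions must sum to 1", call. = FALSE)
  }
  sc <- profiles[, c("s1", "s2", "s3")]
  if (any(!is.na(sc) & sc <= 0)) {
    stop("synth_config: all scales must be > 0", call. = FALSE)
  }
  cfg <- structure(list(n = as.integer(n),
                        class_proportions = as.numeric(class_proportions),
                        profiles = profiles,
                        planted_rules = list(),
                        seed = as.integer(seed)),
                   class = "ctg_synth_config")
  for (r in planted_rules) cfg <- plant_rule(cfg, r)
  cfg
}

#' Add a planted rule to a synthetic configuration
#'
#' Returns a new configuration; the original is unmodified. Regions are
#' carved from existing records (labels overwritten), so `n` is exact and the
#' pre-planting class proportions keep their meaning.
#'
#' @param config a [synth_config()].
#' @param rule a [planted_rule()].
#' @return A new `ctg_synth_config` containing the rule.
#' @export
plant_rule <- function(config, rule) {
  stopifnot(inherits(config, "ctg_synth_config"),
            inherits(rule, "ctg_planted_rule"))
  prof <- config$profiles
  for (nm in names(rule$conditions)) {
    row <- prof[prof$feature == nm, ]
    iv <- rule$conditions[[nm]]
    if (nrow(row) == 1 && row$kind == "truncnorm" &&
        (iv[1] < row$lower || iv[2] > row$upper)) {
      stop("plant_rule: interval for '", nm, "' outside feature domain [",
           row$lower, ", ", row$upper, "]", call. = FALSE)
    }
  }
  for (prev in config$planted_rules) {
    if (prev$target_class != rule$target_class &&
        setequal(names(prev$conditions), names(rule$conditions))) {
      overlaps <- vapply(names(rule$conditions), function(nm) {
        a <- prev$conditions[[nm]]; b <- rule$conditions[[nm]]
        a[1] < b[2] && b[1] < a[2]
      }, logical(1))
      if (all(overlaps)) {
        stop("plant_rule: region overlaps an existing planted region with a ",
             "different target class", call. = FALSE)
      }
    }
  }
  config$planted_rules <- c(config$planted_rules, list(rule))
  config
}

# deterministic stage-local sub-seed from the root seed (kept < 2^31)
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1013904223 * k) %% 2147483647)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

#' Generate a synthetic CTG dataset
#'
#' Class labels are drawn multinomially with the configured proportions;
#' features are drawn per class from the profile table (truncated normals for
#' continuous features, Poisson event counts over a nominal 1800 s trace for
#' event rates); histogram statistics are derived so that
#' `Width = Max - Min` and `Min <= Mode, Median <= Max` hold exactly; planted
#' rule regions are injected last so their purity is exact. Fully
#' reproducible: identical configurations (including seed) give identical
#' datasets.
#'
#' @param config a [synth_config()].
#' @return A [ctg_dataset]. If any class has expected count below 1/2 a
#'   `degenerate proportions` note is appended to the provenance tag.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "ctg_synth_config"))
  n <- config$n
  props <- config$class_proportions
  prof <- config$profiles

  set.seed(.sub_seed(config$seed, 1L))
  labels <- sample.int(3L, n, replace = TRUE, prob = props)

  set.seed(.sub_seed(config$seed, 2L))
  df <- as.data.frame(matrix(0, n, 22))
  names(df) <- c(ctg_feature_names(), "NSP")
  df$NSP <- labels
  trace_s <- 1800

  getp <- function(feature) prof[prof$feature == feature, ]
  # Width is drawn first; variability-block features have their locations
  # scaled by it, inducing the latent variability-factor covariance
  # (Width, Variance, MSTV, DL, Nmax) seen in real CTG histograms
  width_power <- c(Variance = 1, MSTV = 0.5, DL = 0.5, Nmax = 0.5)
  wrow <- getp("Width")
  wloc <- c(wrow$m1, wrow$m2, wrow$m3)[labels]
  wsc <- c(wrow$s1, wrow$s2, wrow$s3)[labels]
  df$Width <- .rtruncnorm(n, wloc, wsc, wrow$lower, wrow$upper)
  wfac <- df$Width / 72

  draw_feature <- function(feature) {
    row <- getp(feature)
    m <- c(row$m1, row$m2, row$m3)[labels]
    s <- c(row$s1, row$s2, row$s3)[labels]
    if (feature %in% names(width_power)) {
      m <- m * wfac^width_power[[feature]]
    }
    switch(row$kind,
      truncnorm = .rtruncnorm(n, m, s, row$lower, row$upper),
      rate = stats::rpois(n, m * trace_s) / trace_s,
      count = stats::rpois(n, m),
      stop("unsupported kind for draw_feature"))
  }

  base_feats <- setdiff(
    prof$feature[prof$kind %in% c("truncnorm", "rate", "count")], "Width")
  # fixed draw order = profile table order, for reproducibility
  for (f in prof$feature) {
    if (f %in% base_feats) df[[f]] <- draw_feature(f)
  }
  # integer-valued features, as in the canonical table
  for (f in c("LB", "ASTV", "ALTV", "Width", "Min", "Variance")) {
    df[[f]] <- round(df[[f]])
  }
  df$MSTV <- round(df$MSTV, 1)
  df$MLTV <- round(df$MLTV, 1)

  df$Max <- df$Min + df$Width
  for (f in c("Mode", "Mean", "Median")) {
    row <- getp(f)
    shift <- c(row$m1, row$m2, row$m3)[labels]
    noise <- stats::rnorm(n, 0, c(row$s1, row$s2, row$s3)[labels])
    df[[f]] <- round(pmin(pmax(df$LB + shift + noise, df$Min), df$Max))
  }
  tendency_probs <- rbind(c(0.08, 0.62, 0.30),
                          c(0.12, 0.60, 0.28),
                          c(0.30, 0.50, 0.20))
  u <- stats::runif(n)
  p1 <- tendency_probs[labels, 1]
  p2 <- p1 + tendency_probs[labels, 2]
  df$Tendency <- ifelse(u < p1, -1, ifelse(u < p2, 0, 1))

  provenance <- sprintf("synthetic (n=%d, seed=%d)", n, config$seed)
  if (any(n * props < 0.5 & props > 0) || any(props == 0)) {
    provenance <- paste0(provenance, "; degenerate proportions")
  }

  # planted regions last, so purity is exact
  if (length(config$planted_rules)) {
    set.seed(.sub_seed(config$seed, 3L))
    taken <- logical(n)
    for (rule in config$planted_rules) {
      m <- max(1L, round(rule$region_fraction * n))
      avail <- which(!taken)
      if (length(avail) < m) {
        stop("generate_dataset: not enough free records to plant rule",
             call. = FALSE)
      }
      idx <- if (length(avail) == 1) avail else sample(avail, m)
      taken[idx] <- TRUE
      for (nm in names(rule$conditions)) {
        iv <- rule$conditions[[nm]]
        draw <- stats::runif(m, iv[1], iv[2])
        # snap planted values to the feature's natural granularity so they
        # are indistinguishable from ordinary records
        grid <- if (nm %in% c("LB", "ASTV", "ALTV", "Width", "Min", "Max",
                              "Nmax", "Nzeros", "Mode", "Mean", "Median",
                              "Variance")) 1
                else if (nm %in% c("MSTV", "MLTV")) 0.1
                else if (nm %in% c("AC", "FM", "UC", "DL", "DS", "DP"))
                  1 / 1800
                else NA
        if (!is.na(grid) && floor(iv[2] / grid) >= ceiling(iv[1] / grid)) {
          draw <- pmin(pmax(round(draw / grid) * grid,
                            ceiling(iv[1] / grid) * grid),
                       floor(iv[2] / grid) * grid)
        }
        df[[nm]][idx] <- draw
      }
      # purity applies to the whole region: records that fall in it
      # naturally are relabelled too, so the stated purity is exact
      in_region <- rep(TRUE, n)
      for (nm in names(rule$conditions)) {
        iv <- rule$conditions[[nm]]
        in_region <- in_region & df[[nm]] >= iv[1] & df[[nm]] <= iv[2]
      }
      ridx <- which(in_region)
      pure <- stats::runif(length(ridx)) < rule$purity
      other <- setdiff(1:3, rule$target_class)
      df$NSP[ridx] <- ifelse(pure, rule$target_class,
                             other[1 + (stats::runif(length(ridx)) < 0.5)])
    }
  }
  df$NSP <- as.integer(df$NSP)
  ctg_dataset(df, provenance = provenance)
}

#' Serialize / deserialize a synthetic configuration
#'
#' Round-trips a [synth_config()] through a YAML key-value file (profiles as a
#' column-wise table; planted rules as nested lists).
#'
#' @param config a `ctg_synth_config`.
#' @param path file path.
#' @return `read_synth_config` returns a `ctg_synth_config`;
#'   `write_synth_config` returns `path` invisibly.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "ctg_synth_config"))
  obj <- list(
    schema = "ctg_synth_config/1",
    n = config$n,
    class_proportions = config$class_proportions,
    seed = config$seed,
    profiles = as.list(config$profiles),
    planted_rules = lapply(config$planted_rules, function(r) {
      list(conditions = lapply(r$conditions, as.numeric),
           target_class = r$target_class, purity = r$purity,
           region_fraction = r$region_fraction)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema) || obj$schema != "ctg_synth_config/1") {
    stop("read_synth_config: unrecognized schema", call. = FALSE)
  }
  prof <- as.data.frame(obj$profiles, stringsAsFactors = FALSE)
  rules <- lapply(obj$planted_rules, function(r) {
    planted_rule(lapply(r$conditions, as.numeric), r$target_class,
                 r$purity, r$region_fraction)
  })
  synth_config(obj$n, as.numeric(obj$class_proportions), prof,
               planted_rules = rules, seed = obj$seed)
}
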