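#' Class-distribution-guided discretization of one feature
#'
#' Builds an ordered interval partition of a feature driven by the fetal-status
#' distribution. Candidate cuts are placed at every boundary between adjacent
#' distinct feature values where the majority class of the records changes
#' (ties in the majority broken toward the lower class code). Cuts are then
#' greedily removed — the adjacent bin pair with the most similar class
#' proportion vectors (L1 distance, ties toward the lower bin index) is merged
#' first — until at most `max_bins` remain and every bin holds at least
#' `min_frac` of the records. The result is deterministic given the data.
#'
#' @param dataset a [ctg_dataset].
#' @param feature feature name.
#' @param max_bins maximum number of bins (>= 2).
#' @param min_frac minimum fraction of records per bin, in (0, 0.5).
#' @return An object of class `ctg_binning`: list with `feature` and `edges`
#'   (strictly increasing; intervals are `[lo, hi)`, last interval closed).
#'   A constant feature yields a single-bin scheme.
#' @export
fit_class_distribution_bins <- function(dataset, feature, max_bins = 6,
                                        min_frac = 0.05) {
  stopifnot(inherits(dataset, "ctg_dataset"),
            feature %in% dataset$feature_names,
            max_bins >= 2, min_frac > 0, min_frac < 0.5)
  x <- dataset$data[[feature]]
  nsp <- dataset$data$NSP
  n <- length(x)
  vals <- sort(unique(x))
  if (length(vals) == 1) {
    return(structure(list(feature = feature, edges = c(vals, vals)),
                     class = "ctg_binning"))
  }
  maj <- vapply(vals, function(v) {
    tab <- tabulate(nsp[x == v], nbins = 3)
    which.max(tab)   # ties -> lower class code
  }, integer(1))
  cuts <- vals[which(diff(maj) != 0) + 1]
  edges <- c(vals[1], cuts, vals[length(vals)])
  edges <- unique(edges)
  if (length(edges) < 2) edges <- c(vals[1], vals[length(vals)])

  repeat {
    nb <- length(edges) - 1
    bin <- .assign_bins(x, edges)
    counts <- tabulate(bin, nbins = nb)
    if (nb <= 1) break
    prop <- t(vapply(seq_len(nb), function(b) {
      cb <- tabulate(nsp[bin == b], nbins = 3)
      if (counts[b] > 0) cb / counts[b] else rep(0, 3)
    }, numeric(3)))
    under <- which(counts / n < min_frac)
    if (length(under)) {
      # absorb the smallest under-mass bin into its more similar neighbor
      # (ties toward the lower index), preserving informative cuts elsewhere
      b <- under[which.min(counts[under])]
      left <- if (b > 1) sum(abs(prop[b, ] - prop[b - 1, ])) else Inf
      right <- if (b < nb) sum(abs(prop[b, ] - prop[b + 1, ])) else Inf
      k <- if (left <= right) b - 1 else b
    } else if (nb > max_bins) {
      d <- vapply(seq_len(nb - 1), function(b) {
        sum(abs(prop[b, ] - prop[b + 1, ]))
      }, numeric(1))
      k <- which.min(d)          # ties -> lower index via which.min
    } else break
    edges <- edges[-(k + 1)]
  }
  structure(list(feature = feature, edges = edges), class = "ctg_binning")
}

# bin index for edges with [lo, hi) intervals, last interval closed
.assign_bins <- function(x, edges) {
  nb <- length(edges) - 1
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > nb] <- nb
  bin
}

#' Construct a discretized condition on one feature
#'
#' Intervals follow the `[lo, hi)` half-open convention; `upper_closed`
#' closes the upper end (used for the last bin of a scheme and for one-sided
#' "greater than" conditions that reach the feature maximum).
#'
#' @param feature feature name.
#' @param lower,upper interval endpoints, `lower < upper`.
#' @param upper_closed logical.
#' @return An object of class `ctg_condition`.
#' @export
rule_condition <- function(feature, lower, upper, upper_closed = FALSE) {
  stopifnot(is.character(feature), lower < upper)
  structure(list(feature = feature, lower = lower, upper = upper,
                 upper_closed = isTRUE(upper_closed)),
            class = "ctg_condition")
}

.condition_matches <- function(cond, data) {
  x <- data[[cond$feature]]
  if (cond$upper_closed) x >= cond$lower & x <= cond$upper
  else x >= cond$lower & x < cond$upper
}

.antecedent_matches <- function(antecedent, data) {
  keep <- rep(TRUE, nrow(data))
  for (cond in antecedent) keep <- keep & .condition_matches(cond, data)
  keep
}

#' Format a condition or rule for display
#'
#' Mirrors the notation of clinical rule tables: `feature: [lo, hi)` for
#' interior intervals and `feature > lo` when a closed union reaches the
#' feature maximum.
#'
#' @param cond a `ctg_condition`.
#' @param feature_max observed maximum of the feature (used to render
#'   one-sided conditions); optional.
#' @return character scalar.
#' @export
format_condition <- function(cond, feature_max = NULL) {
  if (cond$upper_closed && !is.null(feature_max) &&
      cond$upper >= feature_max) {
    sprintf("%s > %g", cond$feature, cond$lower)
  } else {
    sprintf("%s: [%g, %g%s", cond$feature, cond$lower, cond$upper,
            if (cond$upper_closed) "]" else ")")
  }
}

#' Support, confidence and match count of an association rule
#'
#' For a rule `antecedent -> class`: support is the fraction of records
#' matching the antecedent, confidence the fraction of those carrying the
#' consequent class. An empty antecedent matches everything, so support is 1
#' and confidence the class prior. With zero matches the confidence is
#' undefined and flagged (never propagated as NaN).
#'
#' @param antecedent list of [rule_condition()] objects (at most one per
#'   feature).
#' @param consequent NSP class in 1:3.
#' @param dataset a [ctg_dataset].
#' @return list with `support`, `confidence`, `match_count`,
#'   `confidence_defined`.
#' @export
rule_support_confidence <- function(antecedent, consequent, dataset) {
  stopifnot(inherits(dataset, "ctg_dataset"), consequent %in% 1:3)
  feats <- vapply(antecedent, function(c) c$feature, character(1))
  if (anyDuplicated(feats)) {
    stop("rule_support_confidence: at most one condition per feature",
         call. = FALSE)
  }
  unknown <- setdiff(feats, dataset$feature_names)
  if (length(unknown)) {
    stop("rule_support_confidence: unknown feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  df <- dataset$data
  match <- .antecedent_matches(antecedent, df)
  m <- sum(match)
  n <- nrow(df)
  if (m == 0) {
    return(list(support = 0, confidence = NA_real_, match_count = 0L,
                confidence_defined = FALSE))
  }
  list(support = m / n,
       confidence = sum(df$NSP[match] == consequent) / m,
       match_count = as.integer(m),
       confidence_defined = TRUE)
}

# all candidate conditions for a feature's binning scheme: single bins and
# unions of adjacent bins spanning at most half the bins
.candidate_conditions <- function(scheme, max_span = NULL) {
  edges <- scheme$edges
  nb <- length(edges) - 1
  if (nb < 1) return(list())
  if (is.null(max_span)) max_span <- max(1L, ceiling(nb / 2))
  out <- list()
  for (len in seq_len(min(max_span, nb))) {
    for (start in seq_len(nb - len + 1)) {
      lo <- edges[start]
      hi <- edges[start + len]
      if (lo >= hi) next   # degenerate single-value scheme
      out[[length(out) + 1]] <- list(
        cond = rule_condition(scheme$feature, lo, hi,
                              upper_closed = (start + len - 1 == nb)),
        start = start, len = len)
    }
  }
  out
}

#' Forward-stepwise association-rule mining for one target class
#'
#' Greedy confidence-maximizing rule search designed for rare classes, where
#' frequent-itemset miners fail the support threshold and class re-weighting
#' biases the result. Starting from an empty antecedent, each step evaluates —
#' for every feature not yet used — every bin of that feature's scheme and
#' every union of adjacent bins (spanning at most half the bins), and adds
#' the condition that maximizes the confidence of
#' `antecedent + condition -> target_class` subject to the match count
#' staying at or above `min_support`. Ties are broken by higher support, then
#' canonical feature order, then lower bin start index, then shorter span, so
#' the search is fully deterministic. The loop stops at confidence 1, when no
#' candidate strictly increases confidence, when the support floor blocks all
#' candidates, or when every feature is used.
#'
#' @param dataset a [ctg_dataset].
#' @param bins named list of `ctg_binning` schemes (one per candidate
#'   feature), e.g. from [fit_class_distribution_bins()].
#' @param target_class NSP class in 1:3 (must be present in the data).
#' @param min_support minimum number of matching records (>= 1).
#' @return list with `rule` (list `antecedent`, `consequent`, `support`,
#'   `confidence`, `match_count`) and `trace` (class `ctg_rule_trace`:
#'   data.frame of per-step feature, interval, support, confidence, plus a
#'   `stopping_reason` attribute in `confidence_1`, `no_improvement`,
#'   `support_floor`, `feature_exhausted`).
#' @export
forward_stepwise_rule <- function(dataset, bins, target_class,
                                  min_support = 5) {
  stopifnot(inherits(dataset, "ctg_dataset"), target_class %in% 1:3,
            min_support >= 1)
  df <- dataset$data
  if (!any(df$NSP == target_class)) {
    stop("forward_stepwise_rule: target class ", target_class,
         " absent from dataset", call. = FALSE)
  }
  feat_order <- dataset$feature_names
  cand_feats <- intersect(feat_order, names(bins))
  antecedent <- list()
  match <- rep(TRUE, nrow(df))
  conf <- mean(df$NSP == target_class)   # empty antecedent: class prior
  supp <- 1
  steps <- list()
  reason <- NULL

  repeat {
    if (conf >= 1) { reason <- "confidence_1"; break }
    used <- vapply(antecedent, function(c) c$feature, character(1))
    open_feats <- setdiff(cand_feats, used)
    if (!length(open_feats)) { reason <- "feature_exhausted"; break }

    best <- NULL
    any_supported <- FALSE
    for (f in open_feats) {
      fpos <- match(f, feat_order)
      for (cc in .candidate_conditions(bins[[f]])) {
        cmatch <- match & .condition_matches(cc$cond, df)
        m <- sum(cmatch)
        if (m < min_support) next
        any_supported <- TRUE
        cconf <- sum(df$NSP[cmatch] == target_class) / m
        csupp <- m / nrow(df)
        key <- c(-cconf, -csupp, fpos, cc$start, cc$len)
        if (is.null(best) || .lex_lt(key, best$key)) {
          best <- list(cond = cc$cond, conf = cconf, supp = csupp,
                       m = m, key = key, cmatch = cmatch)
        }
      }
    }
    if (!any_supported) { reason <- "support_floor"; break }
    if (is.null(best) || best$conf <= conf) { reason <- "no_improvement"; break }
    antecedent[[length(antecedent) + 1]] <- best$cond
    match <- best$cmatch
    conf <- best$conf
    supp <- best$supp
    steps[[length(steps) + 1]] <- data.frame(
      feature = best$cond$feature, lower = best$cond$lower,
      upper = best$cond$upper, upper_closed = best$cond$upper_closed,
      support = best$supp, confidence = best$conf,
      match_count = best$m, stringsAsFactors = FALSE)
  }

  trace <- if (length(steps)) do.call(rbind, steps) else
    data.frame(feature = character(0), lower = numeric(0),
               upper = numeric(0), upper_closed = logical(0),
               support = numeric(0), confidence = numeric(0),
               match_count = integer(0))
  attr(trace, "stopping_reason") <- reason
  class(trace) <- c("ctg_rule_trace", "data.frame")
  rule <- list(antecedent = antecedent, consequent = as.integer(target_class),
               support = supp, confidence = conf,
               match_count = as.integer(sum(match)))
  list(rule = rule, trace = trace)
}

# lexicographic strictly-less on numeric keys
.lex_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Exhaustive maximal-confidence rule search (oracle)
#'
#' Enumerates every antecedent of at most `max_len` conditions (one per
#' feature, over the same candidate conditions the greedy miner considers)
#' and returns the rule of globally maximal confidence, ties broken by
#' maximal support and then the greedy miner's deterministic ordering.
#' Intended as an independent check on [forward_stepwise_rule()]; refuses to
#' run past `guard` candidates.
#'
#' @inheritParams forward_stepwise_rule
#' @param max_len maximum antecedent size.
#' @param guard maximum number of candidate antecedents to enumerate.
#' @return rule list as in [forward_stepwise_rule()].
#' @export
exhaustive_best_rule <- function(dataset, bins, target_class,
                                 min_support = 5, max_len = 2,
                                 guard = 1e6) {
  stopifnot(inherits(dataset, "ctg_dataset"), target_class %in% 1:3,
            max_len >= 1)
  df <- dataset$data
  if (!any(df$NSP == target_class)) {
    stop("exhaustive_best_rule: target class absent from dataset",
         call. = FALSE)
  }
  feat_order <- dataset$feature_names
  cand_feats <- intersect(feat_order, names(bins))
  conds <- lapply(cand_feats, function(f) .candidate_conditions(bins[[f]]))
  names(conds) <- cand_feats
  ncond <- vapply(conds, length, integer(1))

  total <- 0
  subsets <- list()
  for (len in seq_len(min(max_len, length(cand_feats)))) {
    combs <- utils::combn(length(cand_feats), len, simplify = FALSE)
    for (cb in combs) {
      total <- total + prod(ncond[cb])
      subsets[[length(subsets) + 1]] <- cb
    }
  }
  if (total > guard) {
    stop("exhaustive_best_rule: ", format(total, big.mark = ","),
         " candidate antecedents exceed the enumeration guard of ",
         format(guard, big.mark = ","), call. = FALSE)
  }

  # per-condition match vectors, computed once
  mvecs <- lapply(conds, function(cs) {
    lapply(cs, function(cc) .condition_matches(cc$cond, df))
  })
  is_target <- df$NSP == target_class
  n <- nrow(df)
  best <- NULL
  for (cb in subsets) {
    grid <- expand.grid(lapply(cb, function(fi) seq_len(ncond[fi])),
                        KEEP.OUT.ATTRS = FALSE)
    for (g in seq_len(nrow(grid))) {
      keep <- rep(TRUE, n)
      for (j in seq_along(cb)) {
        keep <- keep & mvecs[[cb[j]]][[grid[g, j][[1]]]]
      }
      m <- sum(keep)
      if (m < min_support) next
      conf <- sum(is_target & keep) / m
      key <- c(-conf, -m / n)
      if (is.null(best) || .lex_lt(key, best$key)) {
        antecedent <- lapply(seq_along(cb), function(j) {
          conds[[cb[j]]][[grid[g, j][[1]]]]$cond
        })
        best <- list(antecedent = antecedent, conf = conf,
                     supp = m / n, m = m, key = key)
      }
    }
  }
  if (is.null(best)) {
    stop("exhaustive_best_rule: no antecedent satisfies the support floor",
         call. = FALSE)
  }
  list(antecedent = best$antecedent,
       consequent = as.integer(target_class),
       support = best$supp, confidence = best$conf,
       match_count = as.integer(best$m))
}

#' @export
print.ctg_rule_trace <- function(x, ...) {
  cat("<ctg_rule_trace> ", nrow(x), " step(s), stopped: ",
      attr(x, "stopping_reason"), "\n", sep = "")
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cond <- rule_condition(x$feature[i], x$lower[i], x$upper[i],
                             x$upper_closed[i])
      cat(sprintf("  + %-24s support %.4f  confidence %.4f  (n=%d)\n",
                  format_condition(cond), x$support[i], x$confidence[i],
                  x$match_count[i]))
    }
  }
  invisible(x)
}

#' Export mined rules as CSV and a readable text block
#'
#' The CSV has one row per rule with `lo`/`hi` column pairs per condition;
#' the text block mirrors a clinical guideline-supplement table, with each
#' condition's standalone confidence printed alongside the conjunction, so
#' both conjunctive and per-feature readings are inspectable.
#'
#' @param rules named list of rule lists (as returned by the miners), names
#'   used as row labels.
#' @param dataset the dataset the rules were mined from (for standalone
#'   confidences).
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_rules <- function(rules, dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(rules), function(nm) {
    r <- rules[[nm]]
    conds <- vapply(r$antecedent, function(c) {
      fmax <- max(dataset$data[[c$feature]])
      format_condition(c, feature_max = fmax)
    }, character(1))
    data.frame(rule = nm, consequent = r$consequent,
               antecedent = paste(conds, collapse = "; "),
               support = r$support, confidence = r$confidence,
               match_count = r$match_count, stringsAsFactors = FALSE)
  })
  csv_path <- file.path(dir, "rules.csv")
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)

  txt_path <- file.path(dir, "rules.txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  for (nm in names(rules)) {
    r <- rules[[nm]]
    writeLines(sprintf("rule %s -> class %d  (support %.4f, confidence %.4f, n=%d)",
                       nm, r$consequent, r$support, r$confidence,
                       r$match_count), con)
    for (c in r$antecedent) {
      alone <- rule_support_confidence(list(c), r$consequent, dataset)
      fmax <- max(dataset$data[[c$feature]])
      writeLines(sprintf("  %-26s standalone confidence %.4f",
                         format_condition(c, feature_max = fmax),
                         alone$confidence), con)
    }
  }
  invisible(c(csv_path, txt_path))
}
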