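#' Spearman rank-correlation matrix of CTG features and fetal status
#'
#' Computes the full Spearman correlation matrix over the 21 features plus
#' `NSP` appended as the 22nd variable. Ties receive average (mid) ranks;
#' `NSP`, a heavily tied ordinal, is ranked like any other variable. Rho is
#' the Pearson correlation of the mid-ranks; two-sided p-values use the
#' large-sample t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom. A constant column has undefined correlations: those
#' entries are `NA` and flagged, never silently zero. No multiple-testing
#' correction is applied to the reported p-values; a Bonferroni-adjusted copy
#' is emitted alongside for convenience.
#'
#' @param dataset a [ctg_dataset] with at least 3 records.
#' @return An object of class `ctg_correlation`: list with `variables`,
#'   `rho` (22 x 22), `p_value`, `p_bonferroni`, `undefined` (logical matrix
#'   flagging entries involving a constant column), `n`.
#' @export
spearman_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "ctg_dataset"))
  df <- dataset$data
  n <- nrow(df)
  if (n < 3) stop("spearman_matrix: need at least 3 records", call. = FALSE)
  vars <- c(dataset$feature_names, "NSP")
  X <- as.matrix(df[, vars])
  constant <- apply(X, 2, function(col) length(unique(col)) == 1)
  R <- apply(X, 2, rank)           # mid-ranks for ties
  rho <- suppressWarnings(stats::cor(R, method = "pearson"))
  undefined <- outer(constant, constant, `|`)
  rho[undefined] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  diag(p) <- NA_real_
  m_tests <- length(vars) * (length(vars) - 1) / 2
  structure(list(variables = vars, rho = rho, p_value = p,
                 p_bonferroni = pmin(p * m_tests, 1),
                 undefined = undefined, n = n),
            class = "ctg_correlation")
}

#' @export
print.ctg_correlation <- function(x, ...) {
  cat("<ctg_correlation> ", length(x$variables), " variables, n = ",
      x$n, "\n", sep = "")
  nsp <- x$rho["NSP", setdiff(x$variables, "NSP")]
  top <- sort(abs(nsp), decreasing = TRUE)[1:5]
  cat("  strongest |rho| with NSP:",
      paste(sprintf("%s=%.2f", names(top), nsp[names(top)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Group features by high mutual Spearman correlation
#'
#' Features are nodes of a graph with an edge wherever `|rho| >= threshold`;
#' the groups are the connected components with two or more members
#' (singletons are discarded). `NSP` is excluded: grouping describes
#' redundancy among features, not their association with the outcome.
#' Ordering is deterministic: groups by their first member's canonical
#' position, members within a group likewise.
#'
#' @param corr a `ctg_correlation` from [spearman_matrix()].
#' @param threshold `|rho|` cutoff in (0, 1); default 0.7, the conventional
#'   "high correlation" mark.
#' @return list of character vectors (feature groups).
#' @export
correlated_groups <- function(corr, threshold = 0.7) {
  stopifnot(inherits(corr, "ctg_correlation"),
            threshold > 0, threshold <= 1)
  feats <- setdiff(corr$variables, "NSP")
  R <- corr$rho[feats, feats]
  adj <- !is.na(R) & abs(R) >= threshold
  diag(adj) <- FALSE
  m <- length(feats)
  comp <- rep(0L, m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  groups <- split(feats, comp)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  first_pos <- vapply(groups, function(g) min(match(g, feats)), integer(1))
  groups <- groups[order(first_pos)]
  lapply(unname(groups), function(g) g[order(match(g, feats))])
}

#' Per-bin fetal-status proportions for one feature
#'
#' The computation behind percentage stacked bar charts of fetal status
#' against a binned feature: bin the feature on the supplied edges (half-open
#' `[lo, hi)` intervals, last bin closed) and tally the class mix per bin.
#' Edges must cover the observed range; if they do not they are auto-extended
#' to the observed min/max with a warning.
#'
#' @param dataset a [ctg_dataset].
#' @param feature feature name.
#' @param edges strictly increasing cut points (length >= 2).
#' @return An object of class `ctg_bin_proportions`: list with `feature`,
#'   `edges`, `count` per bin, `proportions` (bins x 3 matrix, rows summing
#'   to 1 for non-empty bins), `empty` flag per bin.
#' @export
stacked_proportions <- function(dataset, feature, edges) {
  stopifnot(inherits(dataset, "ctg_dataset"),
            feature %in% dataset$feature_names,
            length(edges) >= 2)
  if (any(diff(edges) <= 0)) {
    stop("stacked_proportions: edges must be strictly increasing",
         call. = FALSE)
  }
  x <- dataset$data[[feature]]
  nsp <- dataset$data$NSP
  if (min(x) < edges[1]) {
    warning("stacked_proportions: extending lower edge to observed minimum")
    edges[1] <- min(x)
  }
  if (max(x) > edges[length(edges)]) {
    warning("stacked_proportions: extending upper edge to observed maximum")
    edges[length(edges)] <- max(x)
  }
  nb <- length(edges) - 1
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = FALSE)
  bin[bin > nb] <- nb   # values equal to the top edge close the last bin
  if (any(bin < 1 | bin > nb)) {
    stop("stacked_proportions: internal error, record outside all bins",
         call. = FALSE)
  }
  count <- tabulate(bin, nbins = nb)
  prop <- matrix(NA_real_, nb, 3,
                 dimnames = list(NULL, c("normal", "suspicious", "pathology")))
  for (b in seq_len(nb)) {
    if (count[b] > 0) {
      prop[b, ] <- vapply(1:3, function(k) sum(nsp[bin == b] == k),
                          numeric(1)) / count[b]
    }
  }
  structure(list(feature = feature, edges = edges, count = count,
                 proportions = prop, empty = count == 0),
            class = "ctg_bin_proportions")
}

#' @export
print.ctg_bin_proportions <- function(x, ...) {
  nb <- length(x$count)
  cat("<ctg_bin_proportions> ", x$feature, ", ", nb, " bins\n", sep = "")
  for (b in seq_len(nb)) {
    lab <- sprintf("[%g, %g%s", x$edges[b], x$edges[b + 1],
                   if (b == nb) "]" else ")")
    if (x$empty[b]) {
      cat(sprintf("  %-18s n=%-6d (empty)\n", lab, x$count[b]))
    } else {
      cat(sprintf("  %-18s n=%-6d N %5.1f%%  S %5.1f%%  P %5.1f%%\n",
                  lab, x$count[b], 100 * x$proportions[b, 1],
                  100 * x$proportions[b, 2], 100 * x$proportions[b, 3]))
    }
  }
  invisible(x)
}

#' Default bin edges for the stacked-proportion profiles
#'
#' Equal-width bins (default 10) spanning the observed range, augmented with
#' clinically meaningful landmark cuts where the feature has them
#' (`ASTV`: 18 and 80; `LB`: 111 and 120, bracketing the typical normal
#' baseline band).
#'
#' @param dataset a [ctg_dataset].
#' @param feature feature name.
#' @param n_bins number of equal-width bins before landmarks are added.
#' @return numeric vector of strictly increasing edges.
#' @export
default_bin_edges <- function(dataset, feature, n_bins = 10) {
  x <- dataset$data[[feature]]
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  landmarks <- switch(feature,
                      ASTV = c(18, 80),
                      LB = c(111, 120),
                      numeric(0))
  landmarks <- landmarks[landmarks > min(x) & landmarks < max(x)]
  sort(unique(c(edges, landmarks)))
}

#' Export a correlation result to CSV files
#'
#' Writes the rho matrix, the p-value matrix and the Bonferroni-adjusted
#' p-values as three CSV files with variable names as row and column headers.
#'
#' @param corr a `ctg_correlation`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_correlation_csv <- function(corr, dir) {
  stopifnot(inherits(corr, "ctg_correlation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("spearman_rho.csv", "spearman_p.csv",
                            "spearman_p_bonferroni.csv"))
  mats <- list(corr$rho, corr$p_value, corr$p_bonferroni)
  for (i in seq_along(paths)) {
    utils::write.csv(as.data.frame(mats[[i]]), paths[i], row.names = TRUE)
  }
  invisible(paths)
}
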