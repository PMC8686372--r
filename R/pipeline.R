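#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one of `input` (path to a CTG table) or `synth` (a
#' [synth_config()]) must be given.
#'
#' @param input path to a CTG table readable by [read_ctg_table()], or NULL.
#' @param synth a [synth_config()], or NULL.
#' @param dialect file dialect for `input`.
#' @param group_threshold `|rho|` cutoff for [correlated_groups()].
#' @param profile_features features to profile with [stacked_proportions()].
#' @param n_bins equal-width bins for the profiles.
#' @param rule_classes NSP classes to mine rules for (default normal and
#'   pathology, the classes with clinically actionable rules).
#' @param min_support support floor (record count) for the rule miner.
#' @param max_bins,min_frac discretization controls, see
#'   [fit_class_distribution_bins()].
#' @param sem_presets subset of `c("measurement", "structural")`.
#' @param uc_error_variance see [measurement_model_preset()].
#' @param seed integer seed for any stochastic stage.
#' @return An object of class `ctg_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synth = NULL, dialect = "csv",
                            group_threshold = 0.7,
                            profile_features = c("ASTV", "LB"),
                            n_bins = 10,
                            rule_classes = c(1L, 3L),
                            min_support = 5, max_bins = 6, min_frac = 0.05,
                            sem_presets = c("measurement", "structural"),
                            uc_error_variance = 0,
                            seed = 1L) {
  if (is.null(input) == is.null(synth)) {
    stop("pipeline_config: exactly one of input / synth must be set",
         call. = FALSE)
  }
  if (!is.null(synth)) stopifnot(inherits(synth, "ctg_synth_config"))
  stopifnot(all(sem_presets %in% c("measurement", "structural")),
            all(rule_classes %in% 1:3))
  structure(list(input = input, synth = synth, dialect = dialect,
                 group_threshold = group_threshold,
                 profile_features = profile_features, n_bins = n_bins,
                 rule_classes = as.integer(rule_classes),
                 min_support = min_support, max_bins = max_bins,
                 min_frac = min_frac, sem_presets = sem_presets,
                 uc_error_variance = uc_error_variance,
                 seed = as.integer(seed)),
            class = "ctg_pipeline_config")
}

# content hash of any R object (serialized to a temp file, md5)
.config_hash <- function(x) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 3)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full interpretability pipeline
#'
#' Stages, in order: data loading (or synthesis), validation and class
#' summary; Spearman screening with correlated-feature grouping and per-bin
#' class-proportion profiles; class-distribution discretization and
#' forward-stepwise rule mining per target class; measurement and structural
#' SEM fits with Wald tables, standardized solutions, fit indices and the
#' effect decomposition on the fetal-status outcome. A failure in any stage
#' aborts with a stage-named error. The report is a pure function of the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage transitions.
#' @return An object of class `ctg_report`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ctg_pipeline_config"))
  say <- function(...) if (verbose) message(...)

  say("stage: data")
  dataset <- .stage("data", {
    if (!is.null(config$synth)) generate_dataset(config$synth)
    else read_ctg_table(config$input, dialect = config$dialect)
  })
  say("  ", nrow(dataset$data), " records")
  validation <- .stage("validate", validate_records(dataset, level = "warn"))
  classes <- .stage("class_counts", class_counts(dataset))

  say("stage: screen")
  screening <- .stage("screen", {
    corr <- spearman_matrix(dataset)
    groups <- correlated_groups(corr, threshold = config$group_threshold)
    profiles <- lapply(config$profile_features, function(f) {
      stacked_proportions(dataset, f,
                          default_bin_edges(dataset, f, config$n_bins))
    })
    names(profiles) <- config$profile_features
    list(correlation = corr, groups = groups, profiles = profiles)
  })

  say("stage: mine-rules")
  rules <- .stage("mine_rules", {
    bins <- lapply(dataset$feature_names, function(f) {
      fit_class_distribution_bins(dataset, f, max_bins = config$max_bins,
                                  min_frac = config$min_frac)
    })
    names(bins) <- dataset$feature_names
    out <- lapply(config$rule_classes, function(k) {
      forward_stepwise_rule(dataset, bins, target_class = k,
                            min_support = config$min_support)
    })
    names(out) <- c("normal", "suspicious", "pathology")[config$rule_classes]
    list(bins = bins, mined = out)
  })

  say("stage: fit-sem")
  sem <- .stage("fit_sem", {
    out <- list()
    for (preset in config$sem_presets) {
      model <- if (preset == "measurement") {
        measurement_model_preset(config$uc_error_variance)
      } else {
        structural_model_preset(config$uc_error_variance)
      }
      sdat <- sem_data(dataset$data[, model$obs_names])
      fit <- fit_ml(model, sdat)
      res <- list(model = model, fit = fit,
                  wald = wald_statistics(fit),
                  standardized = standardize_solution(fit),
                  indices = fit_indices(fit))
      if (preset == "structural") {
        res$effects <- effect_decomposition(fit, outcome = "NSP")
      }
      out[[preset]] <- res
    }
    out
  })

  structure(list(config = config, config_hash = .config_hash(config),
                 provenance = list(
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("ctginterp")),
                   dataset_provenance = dataset$provenance),
                 dataset = dataset, validation = validation,
                 classes = classes, screening = screening,
                 rules = rules, sem = sem),
            class = "ctg_report")
}

#' @export
print.ctg_report <- function(x, ...) {
  cat("<ctg_report> config hash ", substr(x$config_hash, 1, 8), "...\n",
      sep = "")
  cat("  records: ", x$classes$n, "  classes: ",
      paste(x$classes$counts, collapse = "/"), "\n", sep = "")
  cat("  correlated groups: ", length(x$screening$groups),
      "  rules mined: ", length(x$rules$mined),
      "  SEM presets: ", paste(names(x$sem), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export an analysis report to a directory
#'
#' One CSV per table, a human-readable text summary, and a machine-readable
#' JSON manifest listing every written file with its MD5 hash. Identical
#' reports export to byte-identical files (no timestamps are written).
#'
#' @param report a [run_pipeline()] result.
#' @param outdir output directory (created if needed; must be writable).
#' @return the manifest as a data.frame (`file`, `md5`), invisibly.
#' @export
export_report <- function(report, outdir) {
  stopifnot(inherits(report, "ctg_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("export_report: directory not writable: ", outdir,
                call. = FALSE)
  unlink(probe)

  files <- character(0)
  put <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files <<- c(files, path)
  }

  cc <- report$classes
  put("class_counts.csv", function(p) {
    utils::write.csv(data.frame(class = names(cc$counts),
                                count = as.integer(cc$counts),
                                proportion = as.numeric(cc$proportions)),
                     p, row.names = FALSE)
  })
  put("spearman_rho.csv", function(p) {
    utils::write.csv(as.data.frame(report$screening$correlation$rho), p)
  })
  put("spearman_p.csv", function(p) {
    utils::write.csv(as.data.frame(report$screening$correlation$p_value), p)
  })
  put("correlated_groups.csv", function(p) {
    g <- report$screening$groups
    df <- if (length(g)) {
      data.frame(group = rep(seq_along(g), lengths(g)),
                 feature = unlist(g), stringsAsFactors = FALSE)
    } else data.frame(group = integer(0), feature = character(0))
    utils::write.csv(df, p, row.names = FALSE)
  })
  for (f in names(report$screening$profiles)) {
    pr <- report$screening$profiles[[f]]
    local({
      f_ <- f; pr_ <- pr
      put(paste0("profile_", f_, ".csv"), function(p) {
        nb <- length(pr_$count)
        utils::write.csv(data.frame(
          lower = pr_$edges[-(nb + 1)], upper = pr_$edges[-1],
          count = pr_$count, pr_$proportions), p, row.names = FALSE)
      })
    })
  }

  mined <- report$rules$mined
  rule_list <- lapply(mined, function(m) m$rule)
  put("rules.csv", function(p) {
    rows <- lapply(names(rule_list), function(nm) {
      r <- rule_list[[nm]]
      conds <- vapply(r$antecedent, function(c) {
        format_condition(c, feature_max = max(
          report$dataset$data[[c$feature]]))
      }, character(1))
      data.frame(rule = nm, consequent = r$consequent,
                 antecedent = paste(conds, collapse = "; "),
                 support = r$support, confidence = r$confidence,
                 match_count = r$match_count, stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(rule = character(0), consequent = integer(0),
                 antecedent = character(0), support = numeric(0),
                 confidence = numeric(0), match_count = integer(0))
    utils::write.csv(df, p, row.names = FALSE)
  })
  put("rule_traces.csv", function(p) {
    rows <- lapply(names(mined), function(nm) {
      tr <- as.data.frame(mined[[nm]]$trace)
      if (nrow(tr)) cbind(rule = nm, step = seq_len(nrow(tr)), tr)
      else NULL
    })
    rows <- Filter(Negate(is.null), rows)
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(rule = character(0), step = integer(0))
    utils::write.csv(df, p, row.names = FALSE)
  })

  for (preset in names(report$sem)) {
    s <- report$sem[[preset]]
    local({
      preset_ <- preset; s_ <- s
      put(paste0("sem_", preset_, "_parameters.csv"), function(p) {
        utils::write.csv(as.data.frame(s_$wald), p, row.names = FALSE)
      })
      put(paste0("sem_", preset_, "_standardized.csv"), function(p) {
        utils::write.csv(s_$standardized$standardized, p, row.names = FALSE)
      })
      put(paste0("sem_", preset_, "_fit_indices.csv"), function(p) {
        utils::write.csv(as.data.frame(s_$indices), p, row.names = FALSE)
      })
      if (!is.null(s_$effects)) {
        put(paste0("sem_", preset_, "_effects.csv"), function(p) {
          utils::write.csv(s_$effects$effects, p, row.names = FALSE)
        })
      }
    })
  }

  put("summary.txt", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("CTG interpretability report")
    w("config hash: %s", report$config_hash)
    w("seed: %d", report$provenance$seed)
    w("dataset: %s (%d records)", report$provenance$dataset_provenance,
      report$classes$n)
    w("classes: normal %d, suspicious %d, pathology %d",
      cc$counts[1], cc$counts[2], cc$counts[3])
    w("validation violations: %d", nrow(report$validation$violations))
    w("correlated groups (|rho| >= %g): %s", report$config$group_threshold,
      paste(vapply(report$screening$groups, paste, character(1),
                   collapse = "+"), collapse = " | "))
    for (nm in names(rule_list)) {
      r <- rule_list[[nm]]
      w("rule[%s]: confidence %.4f support %.4f (n=%d)",
        nm, r$confidence, r$support, r$match_count)
    }
    for (preset in names(report$sem)) {
      s <- report$sem[[preset]]
      w("sem[%s]: F_ML %.6f, converged %s, chisq %.2f",
        preset, s$fit$F_ML, s$fit$converged,
        s$indices$value[s$indices$index == "chisq"])
    }
  })

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
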