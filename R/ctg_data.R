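#' Canonical CTG feature names
#'
#' The 21 diagnostic features of the standard antepartum cardiotocography
#' table, in canonical order, excluding the `NSP` fetal-state label.
#' `LB` is the baseline fetal heart rate (bpm); `AC`, `FM`, `UC`, `DL`, `DS`,
#' `DP` are event rates (events per second); `ASTV`/`ALTV` are percentages of
#' time with abnormal short-/long-term variability; `MSTV`/`MLTV` their mean
#' values (bpm); `Width`, `Min`, `Max`, `Nmax`, `Nzeros`, `Mode`, `Mean`,
#' `Median`, `Variance`, `Tendency` describe the FHR histogram.
#'
#' @return Character vector of length 21.
#' @export
ctg_feature_names <- function() {
  c("LB", "AC", "FM", "UC", "DL", "DS", "DP",
    "ASTV", "MSTV", "ALTV", "MLTV",
    "Width", "Min", "Max", "Nmax", "Nzeros",
    "Mode", "Mean", "Median", "Variance", "Tendency")
}

#' FIGO fetal-status interpretation criteria (documentation constants)
#'
#' The consensus criteria that define the normal / suspicious / pathology
#' classes from baseline, variability and deceleration morphology. Shipped as
#' reference text only; nothing in the pipeline executes these rules.
#'
#' @format A data frame with one row per criterion group (baseline,
#'   variability, other patterns) and one column per fetal-status class.
#' @export
figo_guidelines <- function() {
  data.frame(
    aspect = c("Baseline", "Variability", "Others"),
    normal = c(
      "Between 110 and 150 bpm",
      "Between 5 and 25 bpm",
      ""
    ),
    suspicious = c(
      "Between 100 and 110 bpm or between 150 and 170 bpm",
      "Amplitude of variability between 5 and 10 bpm for more than 40 s",
      "Increased variability above 25 bpm; variable decelerations"
    ),
    pathology = c(
      "Below 100 or above 170 bpm",
      "Persistence of variability of less than 5 bpm for more than 40 s",
      paste("Severe variable or severe repetitive early decelerations;",
            "prolonged or late decelerations; sinusoidal pattern")
    ),
    stringsAsFactors = FALSE
  )
}

#' Construct a CTG dataset object
#'
#' @param data data.frame with the 21 feature columns plus `NSP`.
#' @param provenance free-text source tag.
#' @return An object of class `ctg_dataset`: a list with elements `data`
#'   (data.frame in canonical column order), `feature_names`, `provenance`.
#' @export
ctg_dataset <- function(data, provenance = "unspecified") {
  feats <- ctg_feature_names()
  cols <- c(feats, "NSP")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop("ctg_dataset: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- data[, cols, drop = FALSE]
  for (cn in cols) {
    if (!is.numeric(data[[cn]])) {
      stop("ctg_dataset: column '", cn, "' is not numeric", call. = FALSE)
    }
  }
  rownames(data) <- NULL
  structure(
    list(data = data, feature_names = feats, provenance = provenance),
    class = "ctg_dataset"
  )
}

#' @export
print.ctg_dataset <- function(x, ...) {
  cat("<ctg_dataset> ", nrow(x$data), " records, ",
      length(x$feature_names), " features + NSP\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  cc <- class_counts(x)
  cat(sprintf("  NSP classes: normal %d (%.0f%%), suspicious %d (%.0f%%), pathology %d (%.0f%%)\n",
              cc$counts[1], 100 * cc$proportions[1],
              cc$counts[2], 100 * cc$proportions[2],
              cc$counts[3], 100 * cc$proportions[3]))
  invisible(x)
}

#' @export
dim.ctg_dataset <- function(x) dim(x$data)

#' Read a CTG feature table from disk
#'
#' Reads the 21-feature + `NSP` cardiotocography table from a delimited file
#' or a spreadsheet. Columns are selected by name (case-insensitive), never by
#' position, because column order differs across circulating copies of the
#' dataset. Numeric parsing is locale-independent (dot decimal separator).
#'
#' @param path file location.
#' @param dialect `"csv"` (RFC-4180, header row; also accepts other
#'   single-character delimiters via `sep`) or `"spreadsheet"` (first sheet
#'   containing the 22 named columns; requires the readxl package).
#' @param sep field separator for the csv dialect.
#' @return A [ctg_dataset].
#' @export
read_ctg_table <- function(path, dialect = c("csv", "spreadsheet"), sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("read_ctg_table: file not found: ", path, call. = FALSE)
  }
  if (dialect == "csv") {
    if (file.size(path) == 0) {
      stop("read_ctg_table: empty file: ", path, call. = FALSE)
    }
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character",
                             check.names = FALSE, strip.white = TRUE,
                             quote = "\"", comment.char = "")
    if (nrow(raw) == 0 && ncol(raw) == 0) {
      stop("read_ctg_table: empty file: ", path, call. = FALSE)
    }
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("read_ctg_table: dialect 'spreadsheet' requires the readxl package",
           call. = FALSE)
    }
    sheets <- readxl::excel_sheets(path)
    raw <- NULL
    for (sh in sheets) {
      cand <- readxl::read_excel(path, sheet = sh, col_types = "text",
                                 .name_repair = "minimal")
      cand <- as.data.frame(cand, check.names = FALSE)
      if (all(tolower(c(ctg_feature_names(), "NSP")) %in%
              tolower(trimws(names(cand))))) {
        raw <- cand
        break
      }
    }
    if (is.null(raw)) {
      stop("read_ctg_table: no sheet in ", path,
           " contains the 22 required columns", call. = FALSE)
    }
  }
  .parse_ctg_frame(raw, provenance = path)
}

.parse_ctg_frame <- function(raw, provenance) {
  wanted <- c(ctg_feature_names(), "NSP")
  have <- trimws(names(raw))
  idx <- match(tolower(wanted), tolower(have))
  if (anyNA(idx)) {
    stop("read_ctg_table: missing required column(s): ",
         paste(wanted[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(wanted))
  names(out) <- wanted
  for (k in seq_along(wanted)) {
    col <- trimws(raw[[idx[k]]])
    if (any(!nzchar(col) | is.na(col))) {
      bad <- which(!nzchar(col) | is.na(col))[1]
      stop("read_ctg_table: empty cell at row ", bad,
           ", column '", wanted[k], "' (missing values are not imputed)",
           call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop("read_ctg_table: non-numeric value '", col[bad],
           "' at row ", bad, ", column '", wanted[k], "'", call. = FALSE)
    }
    out[[k]] <- num
  }
  df <- as.data.frame(out, check.names = FALSE)
  nsp <- df$NSP
  if (any(nsp != round(nsp))) {
    bad <- which(nsp != round(nsp))[1]
    stop("read_ctg_table: non-integer NSP label at row ", bad, call. = FALSE)
  }
  df$NSP <- as.integer(round(nsp))
  ctg_dataset(df, provenance = provenance)
}

#' Write a CTG dataset as canonical CSV
#'
#' Deterministic column order (canonical feature order then `NSP`) and
#' 6-significant-digit float formatting, so that write-then-read round-trips
#' reproduce every value.
#'
#' @param dataset a [ctg_dataset].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ctg_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "ctg_dataset"))
  df <- dataset$data
  # 6 significant digits, widened per value to the minimum that round-trips
  fmt_num <- function(x) {
    for (d in 6:17) {
      s <- formatC(x, digits = d, format = "g", flag = "-")
      if (as.numeric(s) == x) return(trimws(s))
    }
    trimws(formatC(x, digits = 17, format = "g", flag = "-"))
  }
  fmt <- lapply(df, function(col) {
    if (is.integer(col)) format(col, scientific = FALSE, trim = TRUE,
                                justify = "none")
    else vapply(col, fmt_num, character(1))
  })
  out <- as.data.frame(fmt, check.names = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate CTG record invariants
#'
#' Checks the domain invariants of each record: `NSP` in `{1,2,3}`;
#' `ASTV`/`ALTV` in `[0,100]`; rates and counts non-negative; `Tendency` in
#' `{-1,0,1}`; histogram consistency (`Width = Max - Min`,
#' `Min <= Mode,Median <= Max`). Histogram consistency may be broken by +-1
#' rounding in circulating copies of the canonical table, so the default level
#' `"warn"` reports rather than rejects.
#'
#' @param dataset a [ctg_dataset].
#' @param level `"warn"` returns the full violation report; `"strict"` raises
#'   on the first violation (the error carries the report).
#' @return An object of class `ctg_validation_report`: data.frame `violations`
#'   with columns `record`, `invariant`, `observed`, plus `counts` per
#'   violation type. Empty report iff every record passes every check.
#' @export
validate_records <- function(dataset, level = c("warn", "strict")) {
  level <- match.arg(level)
  stopifnot(inherits(dataset, "ctg_dataset"))
  df <- dataset$data
  if (nrow(df) == 0) stop("validate_records: empty dataset", call. = FALSE)

  rec <- integer(0); inv <- character(0); obs <- character(0)
  add <- function(idx, name, values) {
    rec <<- c(rec, idx)
    inv <<- c(inv, rep(name, length(idx)))
    obs <<- c(obs, values)
  }
  flag <- function(bad, name, values) {
    if (any(bad)) add(which(bad), name, values[bad])
  }

  flag(!(df$NSP %in% c(1L, 2L, 3L)), "NSP_domain", paste0("NSP=", df$NSP))
  for (f in c("ASTV", "ALTV")) {
    flag(df[[f]] < 0 | df[[f]] > 100, paste0(f, "_range"),
         paste0(f, "=", df[[f]]))
  }
  for (f in c("AC", "FM", "UC", "DL", "DS", "DP", "MSTV", "MLTV",
              "Width", "Nmax", "Nzeros", "Variance")) {
    flag(df[[f]] < 0, paste0(f, "_nonnegative"), paste0(f, "=", df[[f]]))
  }
  for (f in c("Nmax", "Nzeros")) {
    flag(df[[f]] != round(df[[f]]), paste0(f, "_integer"),
         paste0(f, "=", df[[f]]))
  }
  flag(!(df$Tendency %in% c(-1, 0, 1)), "Tendency_domain",
       paste0("Tendency=", df$Tendency))
  flag(df$Width != df$Max - df$Min, "Width_eq_Max_minus_Min",
       paste0("Width=", df$Width, ",Max=", df$Max, ",Min=", df$Min))
  flag(df$Mode < df$Min | df$Mode > df$Max, "Mode_in_histogram_range",
       paste0("Mode=", df$Mode, ",Min=", df$Min, ",Max=", df$Max))
  flag(df$Median < df$Min | df$Median > df$Max, "Median_in_histogram_range",
       paste0("Median=", df$Median, ",Min=", df$Min, ",Max=", df$Max))

  ord <- order(rec, inv)
  violations <- data.frame(record = rec[ord], invariant = inv[ord],
                           observed = obs[ord], stringsAsFactors = FALSE)
  counts <- table(violations$invariant)
  report <- structure(
    list(violations = violations,
         counts = stats::setNames(as.integer(counts), names(counts)),
         n_records = nrow(df)),
    class = "ctg_validation_report"
  )
  if (level == "strict" && nrow(violations) > 0) {
    cond <- structure(
      class = c("ctg_validation_error", "error", "condition"),
      list(message = paste0("validate_records: ", nrow(violations),
                            " invariant violation(s); first: record ",
                            violations$record[1], " ",
                            violations$invariant[1]),
           call = sys.call(-1), report = report)
    )
    stop(cond)
  }
  report
}

#' @export
print.ctg_validation_report <- function(x, ...) {
  cat("<ctg_validation_report> ", nrow(x$violations), " violation(s) across ",
      x$n_records, " records\n", sep = "")
  if (length(x$counts)) {
    for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Fetal-status class counts and proportions
#'
#' @param dataset a [ctg_dataset].
#' @return list with `counts` and `proportions`, both named
#'   `c("normal","suspicious","pathology")` for NSP = 1, 2, 3, plus
#'   `n` and a `proportions_defined` flag (FALSE for an empty dataset).
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "ctg_dataset"))
  nsp <- dataset$data$NSP
  bad <- !(nsp %in% c(1L, 2L, 3L))
  if (any(bad)) {
    stop("class_counts: invalid NSP label(s) at record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  counts <- vapply(1:3, function(k) sum(nsp == k), integer(1))
  names(counts) <- c("normal", "suspicious", "pathology")
  n <- length(nsp)
  if (n == 0) {
    props <- stats::setNames(rep(NA_real_, 3), names(counts))
    return(list(counts = counts, proportions = props, n = 0L,
                proportions_defined = FALSE))
  }
  list(counts = counts, proportions = counts / n, n = n,
       proportions_defined = TRUE)
}
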