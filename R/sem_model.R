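#' Build a latent-variable structural equation model
#'
#' Constructs a LISREL-parameterized model: measurement equations
#' `x = Lambda_x xi + delta`, `y = Lambda_y eta + epsilon` and structural
#' equations `eta = beta eta + Gamma xi + zeta`. Latents that never appear as
#' the target of a path are exogenous (`xi`); latents that do are endogenous
#' (`eta`), and their indicators form the y-block. Each latent needs exactly
#' one scaling constraint: a reference indicator whose loading is fixed at 1,
#' or (exogenous latents only) `NA` to fix the latent variance at 1.
#'
#' @param latents named list: latent name -> character vector of its
#'   indicators. Every indicator belongs to exactly one latent.
#' @param paths data.frame with columns `from`, `to` (latent names);
#'   `NULL` for a pure confirmatory factor model.
#' @param covariances data.frame with columns `a`, `b`: pairs of exogenous
#'   latents whose covariance is free (variances of exogenous latents are
#'   always free unless variance-scaled). Omitted pairs are fixed at 0.
#' @param scaling named character: latent -> reference indicator, or `NA` to
#'   fix an exogenous latent's variance at 1. Every latent must be named.
#' @param fixed_error named numeric: indicator -> fixed unique-error variance
#'   (e.g. 0 for a single-indicator construct measured without error).
#' @return An object of class `sem_model` with the observed-variable order
#'   (`obs_names` = x-block then y-block), parameter matrices
#'   (`Lx`, `Ly`, `Be`, `Ga`, `Ph`, `Ps`, `Td`, `Te`, each a list of
#'   `value` and `free`), and the free-parameter table.
#' @export
build_model <- function(latents, paths = NULL, covariances = NULL,
                        scaling, fixed_error = numeric(0)) {
  stopifnot(is.list(latents), length(latents) >= 1,
            !is.null(names(latents)))
  lat_names <- names(latents)
  all_ind <- unlist(latents, use.names = FALSE)
  dup <- all_ind[duplicated(all_ind)]
  if (length(dup)) {
    stop("build_model: indicator(s) claimed by two latents: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(lat_names %in% names(scaling))) {
    stop("build_model: no scaling constraint for latent(s): ",
         paste(setdiff(lat_names, names(scaling)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(paths)) {
    paths <- data.frame(from = character(0), to = character(0))
  }
  stopifnot(all(paths$from %in% lat_names), all(paths$to %in% lat_names))
  lat_eta <- intersect(lat_names, unique(paths$to))
  lat_xi <- setdiff(lat_names, lat_eta)
  obs_x <- unlist(latents[lat_xi], use.names = FALSE)
  obs_y <- unlist(latents[lat_eta], use.names = FALSE)

  for (L in lat_names) {
    s <- scaling[[L]]
    if (is.na(s)) {
      if (L %in% lat_eta) {
        stop("build_model: endogenous latent '", L,
             "' needs a reference indicator", call. = FALSE)
      }
    } else if (!s %in% latents[[L]]) {
      stop("build_model: reference indicator '", s,
           "' is not an indicator of '", L, "'", call. = FALSE)
    }
  }

  mk <- function(nr, nc, rn, cn) {
    list(value = matrix(0, nr, nc, dimnames = list(rn, cn)),
         free = matrix(FALSE, nr, nc, dimnames = list(rn, cn)))
  }
  Lx <- mk(length(obs_x), length(lat_xi), obs_x, lat_xi)
  Ly <- mk(length(obs_y), length(lat_eta), obs_y, lat_eta)
  Be <- mk(length(lat_eta), length(lat_eta), lat_eta, lat_eta)
  Ga <- mk(length(lat_eta), length(lat_xi), lat_eta, lat_xi)
  Ph <- mk(length(lat_xi), length(lat_xi), lat_xi, lat_xi)
  Ps <- mk(length(lat_eta), length(lat_eta), lat_eta, lat_eta)
  Td <- mk(length(obs_x), length(obs_x), obs_x, obs_x)
  Te <- mk(length(obs_y), length(obs_y), obs_y, obs_y)

  set_loading <- function(M, L, inds) {
    ref <- scaling[[L]]
    for (ind in inds) {
      if (!is.na(ref) && ind == ref) M$value[ind, L] <- 1
      else { M$free[ind, L] <- TRUE; M$value[ind, L] <- NA_real_ }
    }
    M
  }
  for (L in lat_xi) Lx <- set_loading(Lx, L, latents[[L]])
  for (L in lat_eta) Ly <- set_loading(Ly, L, latents[[L]])

  for (i in seq_len(nrow(paths))) {
    from <- paths$from[i]; to <- paths$to[i]
    if (from %in% lat_eta) {
      if (from == to) stop("build_model: self-loop on '", from, "'",
                           call. = FALSE)
      Be$free[to, from] <- TRUE; Be$value[to, from] <- NA_real_
    } else {
      Ga$free[to, from] <- TRUE; Ga$value[to, from] <- NA_real_
    }
  }

  for (L in lat_xi) {
    if (is.na(scaling[[L]])) Ph$value[L, L] <- 1
    else { Ph$free[L, L] <- TRUE; Ph$value[L, L] <- NA_real_ }
  }
  if (!is.null(covariances) && nrow(covariances)) {
    for (i in seq_len(nrow(covariances))) {
      a <- covariances$a[i]; b <- covariances$b[i]
      if (!(a %in% lat_xi && b %in% lat_xi)) {
        stop("build_model: free covariance must join two exogenous latents (",
             a, ", ", b, ")", call. = FALSE)
      }
      Ph$free[a, b] <- Ph$free[b, a] <- TRUE
      Ph$value[a, b] <- Ph$value[b, a] <- NA_real_
    }
  }
  for (L in lat_eta) { Ps$free[L, L] <- TRUE; Ps$value[L, L] <- NA_real_ }

  set_error <- function(M, inds) {
    for (ind in inds) {
      if (ind %in% names(fixed_error)) M$value[ind, ind] <- fixed_error[[ind]]
      else { M$free[ind, ind] <- TRUE; M$value[ind, ind] <- NA_real_ }
    }
    M
  }
  Td <- set_error(Td, obs_x)
  Te <- set_error(Te, obs_y)

  model <- structure(
    list(latents = latents, lat_xi = lat_xi, lat_eta = lat_eta,
         obs_x = obs_x, obs_y = obs_y, obs_names = c(obs_x, obs_y),
         scaling = scaling, paths = paths,
         Lx = Lx, Ly = Ly, Be = Be, Ga = Ga,
         Ph = Ph, Ps = Ps, Td = Td, Te = Te),
    class = "sem_model")
  model$param_table <- .build_param_table(model)
  model$n_free <- nrow(model$param_table)
  model$fill_index <- .fill_index(model)
  model
}

# canonical free-parameter order: Lx, Ly, Ga, Be, Ph (lower tri), Ps, Td, Te
.build_param_table <- function(model) {
  rows <- list()
  add <- function(mat_name, sym = FALSE, kind) {
    M <- model[[mat_name]]
    if (!length(M$free)) return()
    rn <- rownames(M$free); cn <- colnames(M$free)
    for (j in seq_len(ncol(M$free))) {
      for (i in seq_len(nrow(M$free))) {
        if (sym && i < j) next
        if (M$free[i, j]) {
          rows[[length(rows) + 1]] <<- data.frame(
            matrix = mat_name, row = i, col = j,
            label = sprintf("%s[%s,%s]", mat_name, rn[i], cn[j]),
            kind = kind, stringsAsFactors = FALSE)
        }
      }
    }
  }
  add("Lx", kind = "loading"); add("Ly", kind = "loading")
  add("Ga", kind = "path");    add("Be", kind = "path")
  add("Ph", sym = TRUE, kind = "variance")
  add("Ps", sym = TRUE, kind = "variance")
  add("Td", sym = TRUE, kind = "variance")
  add("Te", sym = TRUE, kind = "variance")
  if (!length(rows)) {
    return(data.frame(matrix = character(0), row = integer(0),
                      col = integer(0), label = character(0),
                      kind = character(0)))
  }
  tab <- do.call(rbind, rows)
  tab$kind[tab$kind == "variance" & tab$row != tab$col] <- "covariance"
  rownames(tab) <- NULL
  tab
}

#' @export
print.sem_model <- function(x, ...) {
  cat("<sem_model> ", length(x$obs_names), " observed variables, ",
      length(x$lat_xi), " exogenous + ", length(x$lat_eta),
      " endogenous latents, ", x$n_free, " free parameters\n", sep = "")
  p <- length(x$obs_names)
  cat("  df = ", p * (p + 1) / 2 - x$n_free, "\n", sep = "")
  invisible(x)
}

# fill model matrices from a free-parameter vector (vectorized through
# precomputed linear indices; called once per objective evaluation)
.sem_matrices <- function(model, theta) {
  stopifnot(length(theta) == model$n_free)
  idx <- model$fill_index
  if (is.null(idx)) idx <- .fill_index(model)
  out <- list()
  for (nm in c("Lx", "Ly", "Be", "Ga", "Ph", "Ps", "Td", "Te")) {
    M <- model[[nm]]$value
    ix <- idx[[nm]]
    if (!is.null(ix)) {
      M[ix$lin] <- theta[ix$pos]
      if (!is.null(ix$lin_sym)) M[ix$lin_sym] <- theta[ix$pos_sym]
    }
    out[[nm]] <- M
  }
  out
}

.fill_index <- function(model) {
  tab <- model$param_table
  sym <- c("Ph", "Ps", "Td", "Te")
  idx <- list()
  for (nm in unique(tab$matrix)) {
    rows <- which(tab$matrix == nm)
    nr <- nrow(model[[nm]]$value)
    lin <- (tab$col[rows] - 1) * nr + tab$row[rows]
    entry <- list(pos = rows, lin = lin)
    if (nm %in% sym) {
      off <- rows[tab$row[rows] != tab$col[rows]]
      if (length(off)) {
        entry$lin_sym <- (tab$row[off] - 1) * nr + tab$col[off]
        entry$pos_sym <- off
      }
    }
    idx[[nm]] <- entry
  }
  idx
}

# extract a free-parameter vector from full matrices, first rescaling the
# latent metric so every reference loading equals 1 (identification-invariant)
#' Free-parameter vector from full parameter matrices
#'
#' Maps a complete set of parameter matrices (in any latent metric) onto the
#' model's free-parameter vector, after rescaling each latent so that its
#' reference loading is exactly 1. Useful for expressing a generating
#' parameterization (e.g. unit-variance latents with standardized loadings)
#' in the identification the fitted model uses.
#'
#' @param model a [build_model()] object whose scaling uses reference
#'   indicators.
#' @param mats named list with `Lx`, `Ly`, `Be`, `Ga`, `Ph`, `Ps`, `Td`, `Te`
#'   (entries matching the model's dimensions; missing zero-size blocks may
#'   be omitted).
#' @return numeric vector in the model's canonical free-parameter order.
#' @export
theta_from_matrices <- function(model, mats) {
  full <- .sem_matrices(model, rep(NA_real_, model$n_free))
  for (nm in names(full)) if (!is.null(mats[[nm]])) {
    stopifnot(all(dim(mats[[nm]]) == dim(full[[nm]])))
    full[[nm]] <- mats[[nm]]
    dimnames(full[[nm]]) <- dimnames(model[[nm]]$value)
  }
  d_xi <- rep(1, length(model$lat_xi)); names(d_xi) <- model$lat_xi
  d_eta <- rep(1, length(model$lat_eta)); names(d_eta) <- model$lat_eta
  for (L in model$lat_xi) {
    ref <- model$scaling[[L]]
    if (!is.na(ref)) d_xi[L] <- full$Lx[ref, L]
  }
  for (L in model$lat_eta) {
    ref <- model$scaling[[L]]
    d_eta[L] <- full$Ly[ref, L]
  }
  if (any(c(d_xi, d_eta) == 0)) {
    stop("theta_from_matrices: zero reference loading", call. = FALSE)
  }
  Dx <- diag(d_xi, nrow = length(d_xi)); Dy <- diag(d_eta, nrow = length(d_eta))
  if (length(d_xi)) {
    full$Lx <- full$Lx %*% solve(Dx)
    full$Ph <- Dx %*% full$Ph %*% Dx
  }
  if (length(d_eta)) {
    full$Ly <- full$Ly %*% solve(Dy)
    full$Ps <- Dy %*% full$Ps %*% Dy
    full$Be <- Dy %*% full$Be %*% solve(Dy)
    if (length(d_xi)) full$Ga <- Dy %*% full$Ga %*% solve(Dx)
  }
  tab <- model$param_table
  vapply(seq_len(nrow(tab)), function(k) {
    full[[tab$matrix[k]]][tab$row[k], tab$col[k]]
  }, numeric(1))
}

#' Confirmatory measurement model preset for the CTG latent constructs
#'
#' Five correlated latent constructs over seventeen CTG indicators:
#' variability (`VCat`: Variance as reference, MLTV, MSTV, ALTV, ASTV,
#' Width), baseline (`BCat`: LB ref, Mean, Median, Mode), deceleration
#' (`DCat`: DP ref, DL, Nzeros), acceleration (`ACat`: AC ref, Nmax, FM) and
#' uterine contraction (`UCat`: the single indicator UC, unique error fixed
#' at `uc_error_variance`). All ten pairwise latent covariances are free.
#'
#' @param uc_error_variance fixed unique-error variance for the
#'   single-indicator UC construct (default 0: UC measures UCat without
#'   error).
#' @return a `sem_model`.
#' @export
measurement_model_preset <- function(uc_error_variance = 0) {
  latents <- list(
    VCat = c("Variance", "MLTV", "MSTV", "ALTV", "ASTV", "Width"),
    BCat = c("LB", "Mean", "Median", "Mode"),
    DCat = c("DP", "DL", "Nzeros"),
    ACat = c("AC", "Nmax", "FM"),
    UCat = "UC")
  lat <- names(latents)
  pairs <- utils::combn(lat, 2)
  covs <- data.frame(a = pairs[1, ], b = pairs[2, ],
                     stringsAsFactors = FALSE)
  build_model(
    latents,
    paths = NULL,
    covariances = covs,
    scaling = c(VCat = "Variance", BCat = "LB", DCat = "DP",
                ACat = "AC", UCat = "UC"),
    fixed_error = c(UC = uc_error_variance))
}

#' Structural model preset for fetal-status assessment
#'
#' The trimmed structural model: MLTV is dropped from the variability
#' construct (its loading fails the Wald test in the measurement stage), the
#' fetal-status outcome `NSP` enters as the single errorless indicator of an
#' outcome construct, and the paths are variability -> baseline,
#' uterine contraction -> deceleration, and acceleration / baseline /
#' deceleration -> fetal status, with a free covariance between the
#' variability and uterine-contraction constructs. References per latent:
#' ALTV, LB, DP, AC, UC, NSP.
#'
#' @inheritParams measurement_model_preset
#' @return a `sem_model` whose observed variables include `NSP`.
#' @export
structural_model_preset <- function(uc_error_variance = 0) {
  latents <- list(
    VCat = c("Variance", "MSTV", "ALTV", "ASTV", "Width"),
    UCat = "UC",
    ACat = c("AC", "Nmax", "FM"),
    BCat = c("LB", "Mean", "Median", "Mode"),
    DCat = c("DP", "DL", "Nzeros"),
    FStat = "NSP")
  paths <- data.frame(
    from = c("VCat", "UCat", "ACat", "BCat", "DCat"),
    to   = c("BCat", "DCat", "FStat", "FStat", "FStat"),
    stringsAsFactors = FALSE)
  build_model(
    latents,
    paths = paths,
    covariances = data.frame(a = "VCat", b = "UCat",
                             stringsAsFactors = FALSE),
    scaling = c(VCat = "ALTV", UCat = "UC", ACat = "AC",
                BCat = "LB", DCat = "DP", FStat = "NSP"),
    fixed_error = c(UC = uc_error_variance, NSP = 0))
}
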