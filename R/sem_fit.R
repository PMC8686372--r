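#' Assemble sample data for SEM fitting
#'
#' @param x either a numeric matrix / data.frame of observations (rows =
#'   records) or, with `cov = TRUE`, a sample covariance matrix.
#' @param n sample size; required when `x` is a covariance matrix.
#' @param cov logical: is `x` already a covariance matrix?
#' @return An object of class `sem_data`: list with `S` (covariance,
#'   denominator `n - 1`), `n`, `variables`.
#' @export
sem_data <- function(x, n = NULL, cov = FALSE) {
  if (cov) {
    S <- as.matrix(x)
    stopifnot(!is.null(n), nrow(S) == ncol(S))
    if (max(abs(S - t(S))) > 1e-8) {
      stop("sem_data: covariance matrix is not symmetric", call. = FALSE)
    }
    S <- (S + t(S)) / 2
  } else {
    x <- as.matrix(x)
    if (anyNA(x)) {
      stop("sem_data: missing values are not supported", call. = FALSE)
    }
    n <- nrow(x)
    S <- stats::cov(x)      # denominator n - 1
  }
  if (is.null(colnames(S))) {
    stop("sem_data: variables must be named", call. = FALSE)
  }
  if (n <= nrow(S)) {
    stop("sem_data: sample size must exceed the number of variables",
         call. = FALSE)
  }
  structure(list(S = S, n = as.integer(n), variables = colnames(S)),
            class = "sem_data")
}

#' Model-implied covariance matrix
#'
#' Standard LISREL composition: exogenous latent covariances are propagated
#' through the loadings; endogenous latent covariances are obtained from the
#' reduced structural form `eta = (I - beta)^{-1} (Gamma xi + zeta)`; unique
#' error (co)variances are added. Symmetric by construction.
#'
#' @param model a [build_model()] object.
#' @param params numeric free-parameter vector (canonical order) or a named
#'   list of full matrices accepted by [theta_from_matrices()].
#' @return covariance matrix over `model$obs_names`.
#' @export
implied_covariance <- function(model, params) {
  m <- .resolve_matrices(model, params)
  .implied_from_matrices(model, m)$Sigma
}

.resolve_matrices <- function(model, params) {
  if (is.list(params) && !is.null(params$Lx)) {
    full <- .sem_matrices(model, rep(0, model$n_free))
    for (nm in names(full)) if (!is.null(params[[nm]])) {
      stopifnot(all(dim(params[[nm]]) == dim(full[[nm]])))
      full[[nm]] <- params[[nm]]
      dimnames(full[[nm]]) <- dimnames(model[[nm]]$value)
    }
    full
  } else {
    .sem_matrices(model, as.numeric(params))
  }
}

.implied_from_matrices <- function(model, m) {
  nx <- length(model$obs_x); ny <- length(model$obs_y)
  ne <- length(model$lat_eta)
  if (ne > 0) {
    ImB <- diag(ne) - m$Be
    A <- tryCatch(solve(ImB), error = function(e) {
      stop("implied_covariance: (I - beta) is singular", call. = FALSE)
    })
    C_eta <- A %*% (m$Ga %*% m$Ph %*% t(m$Ga) + m$Ps) %*% t(A)
    C_eta_xi <- A %*% m$Ga %*% m$Ph
  } else {
    A <- matrix(0, 0, 0)
    C_eta <- matrix(0, 0, 0)
    C_eta_xi <- matrix(0, 0, length(model$lat_xi))
  }
  Sigma <- matrix(0, nx + ny, nx + ny,
                  dimnames = list(model$obs_names, model$obs_names))
  if (nx > 0) {
    Sigma[1:nx, 1:nx] <- m$Lx %*% m$Ph %*% t(m$Lx) + m$Td
  }
  if (ny > 0) {
    yi <- nx + seq_len(ny)
    Sigma[yi, yi] <- m$Ly %*% C_eta %*% t(m$Ly) + m$Te
    if (nx > 0) {
      Syx <- m$Ly %*% C_eta_xi %*% t(m$Lx)
      Sigma[yi, 1:nx] <- Syx
      Sigma[1:nx, yi] <- t(Syx)
    }
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  list(Sigma = Sigma, C_eta = C_eta, C_eta_xi = C_eta_xi, A = A)
}

#' Maximum-likelihood discrepancy between sample and implied covariance
#'
#' `F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p`; non-negative, zero iff
#' `Sigma = S`.
#'
#' @param S sample covariance (positive definite).
#' @param Sigma implied covariance (positive definite, same order).
#' @return scalar discrepancy.
#' @export
fml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  stopifnot(nrow(Sigma) == p, ncol(S) == p, ncol(Sigma) == p)
  chS <- tryCatch(chol(S), error = function(e) {
    stop("fml_discrepancy: sample covariance S is not positive definite",
         call. = FALSE)
  })
  chSig <- tryCatch(chol(Sigma), error = function(e) {
    stop("fml_discrepancy: implied covariance Sigma is not positive definite",
         call. = FALSE)
  })
  ldS <- 2 * sum(log(diag(chS)))
  ldSig <- 2 * sum(log(diag(chSig)))
  tr <- sum(diag(chol2inv(chSig) %*% S))
  ldSig + tr - ldS - p
}

# deterministic covariance-based starting values: each latent is proxied by
# its reference indicator with half that indicator's variance; loadings,
# structural paths and latent covariances start at the corresponding
# proxy-regression / proxy-covariance values, uniquenesses at half the
# observed variance
.start_values <- function(model, S) {
  lat_all <- c(model$lat_xi, model$lat_eta)
  refs <- vapply(lat_all, function(L) {
    r <- model$scaling[[L]]
    if (is.na(r)) model$latents[[L]][1] else r
  }, character(1))
  phi0 <- function(L) 0.5 * S[refs[L], refs[L]]
  tab <- model$param_table
  theta <- numeric(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    mnm <- tab$matrix[k]; i <- tab$row[k]; j <- tab$col[k]
    theta[k] <- switch(mnm,
      Lx = {
        L <- model$lat_xi[j]
        S[model$obs_x[i], refs[L]] / phi0(L)
      },
      Ly = {
        L <- model$lat_eta[j]
        S[model$obs_y[i], refs[L]] / phi0(L)
      },
      Ga = {
        rf <- refs[model$lat_xi[j]]
        S[refs[model$lat_eta[i]], rf] / S[rf, rf]
      },
      Be = {
        rf <- refs[model$lat_eta[j]]
        S[refs[model$lat_eta[i]], rf] / S[rf, rf]
      },
      Ph = if (i == j) phi0(model$lat_xi[i]) else
        0.5 * S[refs[model$lat_xi[i]], refs[model$lat_xi[j]]],
      Ps = if (i == j) 0.4 * S[refs[model$lat_eta[i]],
                               refs[model$lat_eta[i]]] else 0,
      Td = 0.5 * S[model$obs_x[i], model$obs_x[i]],
      Te = 0.5 * S[model$obs_y[i], model$obs_y[i]])
  }
  theta
}

# central-difference gradient (cheap polish-stage gradient)
.cd_grad <- function(fn, theta, h = 1e-6) {
  vapply(seq_along(theta), function(k) {
    hk <- h * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + hk
    tm <- theta; tm[k] <- tm[k] - hk
    (fn(tp) - fn(tm)) / (2 * hk)
  }, numeric(1))
}

# central-difference Hessian with a small step, so that parameters close to
# an admissibility boundary (e.g. a latent correlation near +-1) are not
# perturbed into the non-positive-definite region
.cd_hessian <- function(fn, theta, h = 1e-4) {
  k <- length(theta)
  hs <- h * pmax(1, abs(theta))
  f0 <- fn(theta)
  H <- matrix(NA_real_, k, k)
  shift <- function(i, s) { t <- theta; t[i] <- t[i] + s; t }
  for (i in seq_len(k)) {
    H[i, i] <- (fn(shift(i, hs[i])) - 2 * f0 + fn(shift(i, -hs[i]))) /
      hs[i]^2
    for (j in seq_len(i - 1)) {
      tpp <- shift(i, hs[i]); tpp[j] <- tpp[j] + hs[j]
      tpm <- shift(i, hs[i]); tpm[j] <- tpm[j] - hs[j]
      tmp <- shift(i, -hs[i]); tmp[j] <- tmp[j] + hs[j]
      tmm <- shift(i, -hs[i]); tmm[j] <- tmm[j] - hs[j]
      H[i, j] <- H[j, i] <-
        (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * hs[i] * hs[j])
    }
  }
  H
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy [fml_discrepancy()] over the free parameters
#' with quasi-Newton iterations (PORT routines via [stats::nlminb()]).
#' Standard errors come from the inverse numerical Hessian of the
#' discrepancy scaled by `2/(n-1)` (the expected-information approximation).
#' Non-convergence is returned as a flagged fit, never a silent answer; a
#' negative estimated variance (Heywood case) is flagged and, only when
#' `bound_variances = TRUE`, prevented by a small positive floor.
#'
#' @param model a [build_model()] object.
#' @param data a [sem_data()] whose variables cover `model$obs_names`.
#' @param start `"auto"` or a numeric vector of starting values in canonical
#'   free-parameter order.
#' @param bound_variances logical: constrain variance parameters to
#'   `>= 1e-6` during optimization.
#' @param se logical: compute standard errors (numerical Hessian).
#' @return An object of class `sem_fit`: estimates with labels, `Sigma_hat`,
#'   `F_ML`, `se`, `vcov`, `converged`, `iterations`, `grad_norm`,
#'   `heywood`, plus the model and data for downstream summaries.
#' @export
fit_ml <- function(model, data, start = "auto", bound_variances = FALSE,
                   se = TRUE) {
  stopifnot(inherits(model, "sem_model"), inherits(data, "sem_data"))
  missing <- setdiff(model$obs_names, data$variables)
  if (length(missing)) {
    stop("fit_ml: data lack model variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  S <- data$S[model$obs_names, model$obs_names]
  p <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("fit_ml: sample covariance is not positive definite", call. = FALSE)
  }
  df <- p * (p + 1) / 2 - model$n_free
  if (df < 0) {
    stop("fit_ml: model has negative degrees of freedom (", df,
         "); not identified", call. = FALSE)
  }
  ldS <- determinant(S, logarithm = TRUE)$modulus[1]

  objective <- function(theta) {
    m <- .sem_matrices(model, theta)
    Sig <- tryCatch(.implied_from_matrices(model, m)$Sigma,
                    error = function(e) NULL)
    if (is.null(Sig)) return(1e10)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(diag(chol2inv(ch) %*% S)) - ldS - p
  }

  theta0 <- if (identical(start, "auto")) .start_values(model, S)
            else { stopifnot(length(start) == model$n_free); as.numeric(start) }
  lower <- rep(-Inf, model$n_free)
  if (bound_variances) {
    is_var <- model$param_table$kind == "variance"
    lower[is_var] <- 1e-6
    theta0[is_var] <- pmax(theta0[is_var], 1e-6)
  }
  opt <- stats::nlminb(theta0, objective, lower = lower,
                       control = list(eval.max = 20000, iter.max = 5000,
                                      rel.tol = 1e-12, x.tol = 1e-12))
  # gradient-assisted polish to push the gradient norm toward machine zero
  polish <- stats::nlminb(opt$par, objective,
                          gradient = function(t) .cd_grad(objective, t),
                          lower = lower,
                          control = list(eval.max = 2000, iter.max = 500,
                                         rel.tol = 1e-15))
  if (polish$objective <= opt$objective) {
    opt$par <- polish$par
    opt$objective <- polish$objective
    opt$iterations <- opt$iterations + polish$iterations
  }
  # Newton refinement: quadratic convergence to the stationary point, so the
  # standardized solution is reproducible to near machine precision
  for (it in 1:3) {
    g <- .cd_grad(objective, opt$par)
    if (max(abs(g)) < 1e-10) break
    H <- tryCatch(.cd_hessian(objective, opt$par), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- opt$par - step
    if (bound_variances) cand <- pmax(cand, lower)
    fc <- objective(cand)
    if (fc <= opt$objective + 1e-12 &&
        max(abs(.cd_grad(objective, cand))) < max(abs(g))) {
      opt$par <- cand
      opt$objective <- fc
    } else break
  }
  theta <- opt$par
  grad <- tryCatch(.cd_grad(objective, theta),
                   error = function(e) rep(NA_real_, length(theta)))
  grad_norm <- max(abs(grad))
  converged <- (is.finite(grad_norm) && grad_norm < 1e-4) ||
    opt$convergence == 0 || polish$convergence == 0
  names(theta) <- model$param_table$label
  Sigma_hat <- implied_covariance(model, theta)
  F_ML <- objective(theta)

  se_vec <- rep(NA_real_, length(theta))
  vc <- NULL
  singular_info <- FALSE
  if (se && model$n_free > 0) {
    H <- tryCatch(.cd_hessian(objective, theta),
                  error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(2 / (data$n - 1) * solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(diag(vc) > 0)) {
        se_vec <- sqrt(diag(vc))
      } else {
        singular_info <- TRUE
        if (!is.null(vc)) se_vec <- sqrt(ifelse(diag(vc) > 0, diag(vc), NA))
      }
    } else singular_info <- TRUE
  }
  names(se_vec) <- names(theta)

  var_idx <- model$param_table$kind == "variance"
  heywood <- any(theta[var_idx] < 0)

  structure(list(model = model, data = list(S = S, n = data$n),
                 theta = theta, Sigma_hat = Sigma_hat, F_ML = F_ML,
                 se = se_vec, vcov = vc, converged = converged,
                 iterations = opt$iterations, grad_norm = grad_norm,
                 heywood = heywood, singular_information = singular_info,
                 df = df),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> F_ML = ", format(x$F_ML, digits = 6),
      ", df = ", x$df,
      ", converged = ", x$converged,
      if (x$heywood) " [Heywood case]" else "", "\n", sep = "")
  cat("  ", x$model$n_free, " free parameters, gradient norm ",
      format(x$grad_norm, digits = 3), ", ", x$iterations,
      " iterations\n", sep = "")
  invisible(x)
}

# model-implied latent covariance over c(lat_xi, lat_eta)
.latent_covariance <- function(model, mats) {
  parts <- .implied_from_matrices(model, mats)
  nxi <- length(model$lat_xi); ne <- length(model$lat_eta)
  C <- matrix(0, nxi + ne, nxi + ne,
              dimnames = list(c(model$lat_xi, model$lat_eta),
                              c(model$lat_xi, model$lat_eta)))
  if (nxi) C[1:nxi, 1:nxi] <- mats$Ph
  if (ne) {
    ei <- nxi + seq_len(ne)
    C[ei, ei] <- parts$C_eta
    if (nxi) {
      C[ei, 1:nxi] <- parts$C_eta_xi
      C[1:nxi, ei] <- t(parts$C_eta_xi)
    }
  }
  C
}

#' Standardized solution of a fitted SEM
#'
#' Rescales every loading and structural path so that all observed and
#' latent variables have unit variance, using model-implied standard
#' deviations; latent covariances become correlations. The solution is
#' invariant to affine rescaling of the raw indicators. Sign convention:
#' each latent's reference indicator must load positively; any latent
#' violating it is sign-flipped (the latent with all of its loadings, paths
#' and correlations) before reporting.
#'
#' @param fit a [fit_ml()] result.
#' @param model the model (defaults to the one stored in the fit).
#' @return list with `loadings` (data.frame indicator, latent, est, est_std),
#'   `paths` (from, to, est, est_std), `latent_corr` (correlation matrix over
#'   all latents), `error_std` (standardized unique variances), and
#'   `standardized` (tidy data.frame of every reported coefficient with
#'   columns lhs, op, rhs, est_std).
#' @export
standardize_solution <- function(fit, model = fit$model) {
  stopifnot(inherits(fit, "sem_fit"))
  mats <- .sem_matrices(model, fit$theta)
  C_lat <- .latent_covariance(model, mats)
  sd_lat <- sqrt(diag(C_lat))
  if (any(sd_lat <= 0)) {
    stop("standardize_solution: zero implied latent variance", call. = FALSE)
  }
  sd_obs <- sqrt(diag(fit$Sigma_hat))
  if (any(sd_obs <= 0)) {
    stop("standardize_solution: zero implied observed variance",
         call. = FALSE)
  }
  lat_all <- c(model$lat_xi, model$lat_eta)

  Lam <- matrix(0, length(model$obs_names), length(lat_all),
                dimnames = list(model$obs_names, lat_all))
  if (length(model$obs_x)) Lam[model$obs_x, model$lat_xi] <- mats$Lx
  if (length(model$obs_y)) Lam[model$obs_y, model$lat_eta] <- mats$Ly
  Lam_std <- Lam * outer(1 / sd_obs[model$obs_names], sd_lat[lat_all])

  # combined structural coefficient matrix over all latents (target x source)
  B <- matrix(0, length(lat_all), length(lat_all),
              dimnames = list(lat_all, lat_all))
  if (length(model$lat_eta)) {
    B[model$lat_eta, model$lat_eta] <- mats$Be
    if (length(model$lat_xi)) B[model$lat_eta, model$lat_xi] <- mats$Ga
  }
  B_std <- B * outer(1 / sd_lat, sd_lat)
  R_lat <- stats::cov2cor(C_lat)

  # positive-reference-loading sign convention
  flip <- rep(1, length(lat_all)); names(flip) <- lat_all
  for (L in lat_all) {
    ref <- model$scaling[[L]]
    ind <- if (!is.na(ref)) ref else model$latents[[L]][1]
    if (Lam_std[ind, L] < 0) flip[L] <- -1
  }
  D <- diag(flip, nrow = length(flip))
  Lam_std <- Lam_std %*% D
  B_std <- D %*% B_std %*% D
  R_lat <- D %*% R_lat %*% D
  dimnames(Lam_std) <- list(model$obs_names, lat_all)
  dimnames(B_std) <- dimnames(R_lat) <- list(lat_all, lat_all)

  load_rows <- list()
  for (L in lat_all) {
    for (ind in model$latents[[L]]) {
      load_rows[[length(load_rows) + 1]] <- data.frame(
        indicator = ind, latent = L,
        est = Lam[ind, L] * flip[L], est_std = Lam_std[ind, L],
        stringsAsFactors = FALSE)
    }
  }
  loadings <- do.call(rbind, load_rows)

  path_rows <- list()
  if (nrow(model$paths)) {
    for (i in seq_len(nrow(model$paths))) {
      f <- model$paths$from[i]; t <- model$paths$to[i]
      path_rows[[length(path_rows) + 1]] <- data.frame(
        from = f, to = t, est = B[t, f] * flip[t] * flip[f],
        est_std = B_std[t, f], stringsAsFactors = FALSE)
    }
  }
  paths <- if (length(path_rows)) do.call(rbind, path_rows) else
    data.frame(from = character(0), to = character(0),
               est = numeric(0), est_std = numeric(0))

  err_all <- c(if (length(model$obs_x)) diag(mats$Td) else numeric(0),
               if (length(model$obs_y)) diag(mats$Te) else numeric(0))
  names(err_all) <- model$obs_names
  error_std <- err_all / sd_obs[model$obs_names]^2

  tidy <- data.frame(lhs = loadings$indicator, op = "<-",
                     rhs = loadings$latent, est_std = loadings$est_std,
                     stringsAsFactors = FALSE)
  if (nrow(paths)) {
    tidy <- rbind(tidy, data.frame(lhs = paths$to, op = "<-",
                                   rhs = paths$from, est_std = paths$est_std,
                                   stringsAsFactors = FALSE))
  }
  free_cov <- model$param_table[model$param_table$kind == "covariance" &
                                  model$param_table$matrix == "Ph", ]
  if (nrow(free_cov)) {
    tidy <- rbind(tidy, data.frame(
      lhs = model$lat_xi[free_cov$row], op = "<->",
      rhs = model$lat_xi[free_cov$col],
      est_std = R_lat[cbind(free_cov$row, free_cov$col)],
      stringsAsFactors = FALSE))
  }
  list(loadings = loadings, paths = paths, latent_corr = R_lat,
       error_std = error_std, standardized = tidy, sign_flip = flip,
       B_std = B_std, Lam_std = Lam_std)
}

#' Wald statistics for the free parameters
#'
#' Critical ratio `C.R. = estimate / SE` with two-sided normal p-values;
#' fixed parameters (reference loadings, fixed error variances) carry no
#' test statistic. Parameters with `p < 0.001` are marked `***`.
#'
#' @param fit a converged [fit_ml()] result.
#' @return data.frame of class `sem_wald_table` with columns `label`,
#'   `kind`, `estimate`, `se`, `cr`, `p`, `sig`.
#' @export
wald_statistics <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (fit$singular_information) {
    warning("wald_statistics: information matrix singular; ",
            "standard errors flagged NA where undefined")
  }
  est <- fit$theta
  se <- fit$se
  cr <- ifelse(is.na(se) | se == 0, NA_real_, est / se)
  p <- 2 * stats::pnorm(-abs(cr))
  sig <- ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  out <- data.frame(label = fit$model$param_table$label,
                    kind = fit$model$param_table$kind,
                    estimate = unname(est), se = unname(se),
                    cr = unname(cr), p = unname(p), sig = sig,
                    stringsAsFactors = FALSE)
  class(out) <- c("sem_wald_table", "data.frame")
  out
}

#' Direct, indirect and total effects on an outcome
#'
#' Standardized effect decomposition from the standardized path system:
#' total effects accumulate over all directed paths via
#' `(I - B)^-1 - I`; the indirect effect is total minus direct. When the
#' outcome is an observed indicator, effects pass through its standardized
#' loading. Two-step mediation chains are reported with their per-path
#' products. Only recursive (acyclic) path systems are supported.
#'
#' @param fit a converged [fit_ml()] result.
#' @param model the model (defaults to the fit's).
#' @param outcome a latent name or an observed indicator name.
#' @return An object of class `sem_effects`: data.frame `effects`
#'   (source, direct, indirect, total) over all latent sources, plus
#'   `chains` (two-step mediation products).
#' @export
effect_decomposition <- function(fit, model = fit$model, outcome) {
  std <- standardize_solution(fit, model)
  lat_all <- c(model$lat_xi, model$lat_eta)
  B <- std$B_std

  # recursivity check: B must be nilpotent
  P <- (B != 0) * 1
  Acc <- P
  for (k in seq_len(nrow(P))) Acc <- Acc %*% P
  if (any(abs(Acc) > 0)) {
    stop("effect_decomposition: cyclic path system is not supported",
         call. = FALSE)
  }
  total_lat <- solve(diag(nrow(B)) - B) - diag(nrow(B))

  if (outcome %in% lat_all) {
    w <- stats::setNames(rep(0, length(lat_all)), lat_all)
    w[outcome] <- 1
    direct_row <- B[outcome, ]
    total_row <- total_lat[outcome, ]
    target_lat <- outcome
  } else if (outcome %in% model$obs_names) {
    target_lat <- NULL
    for (L in lat_all) if (outcome %in% model$latents[[L]]) target_lat <- L
    if (is.null(target_lat)) {
      stop("effect_decomposition: outcome '", outcome,
           "' not in the model", call. = FALSE)
    }
    lam <- std$Lam_std[outcome, target_lat]
    direct_row <- lam * B[target_lat, ]
    total_row <- lam * total_lat[target_lat, ]
  } else {
    stop("effect_decomposition: unknown outcome '", outcome, "'",
         call. = FALSE)
  }

  sources <- setdiff(lat_all, target_lat)
  eff <- data.frame(source = sources,
                    direct = direct_row[sources],
                    total = total_row[sources],
                    stringsAsFactors = FALSE)
  eff$indirect <- eff$total - eff$direct
  eff <- eff[, c("source", "direct", "indirect", "total")]
  rownames(eff) <- NULL

  chains <- list()
  for (s in sources) {
    for (mediator in setdiff(lat_all, c(s, target_lat))) {
      a <- B[mediator, s]; b <- B[target_lat, mediator]
      if (a != 0 && b != 0) {
        chains[[length(chains) + 1]] <- data.frame(
          source = s, mediator = mediator, target = target_lat,
          step1 = a, step2 = b, product = a * b,
          stringsAsFactors = FALSE)
      }
    }
  }
  chains <- if (length(chains)) do.call(rbind, chains) else
    data.frame(source = character(0), mediator = character(0),
               target = character(0), step1 = numeric(0),
               step2 = numeric(0), product = numeric(0))
  structure(list(outcome = outcome, effects = eff, chains = chains),
            class = "sem_effects")
}

#' @export
print.sem_effects <- function(x, ...) {
  cat("<sem_effects> standardized effects on ", x$outcome, "\n", sep = "")
  print(format(x$effects, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Global fit indices for a fitted SEM
#'
#' Chi-square `(n-1) F_ML` with `df = p(p+1)/2 - #free`; CFI and TLI against
#' the independence baseline (diagonal implied covariance, whose ML solution
#' is closed-form); RMSEA with a 90 percent interval from the noncentral
#' chi-square; SRMR from the correlation-scale residuals of `S` versus
#' `Sigma(theta)`. A just-identified model (`df = 0`) reports RMSEA 0 with a
#' flag.
#'
#' @param fit a converged [fit_ml()] result.
#' @param data optional [sem_data()] (defaults to the sample stored in the
#'   fit).
#' @return data.frame of class `sem_fit_indices` with one row per index.
#' @export
fit_indices <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  S <- if (is.null(data)) fit$data$S else
    data$S[fit$model$obs_names, fit$model$obs_names]
  n <- if (is.null(data)) fit$data$n else data$n
  p <- nrow(S)
  df <- fit$df
  chisq <- (n - 1) * fit$F_ML

  # independence baseline: Sigma = diag(S) is the closed-form ML solution
  F_base <- sum(log(diag(S))) -
    determinant(S, logarithm = TRUE)$modulus[1]
  chisq_b <- (n - 1) * F_base
  df_b <- p * (p - 1) / 2

  cfi <- 1 - max(chisq - df, 0) / max(chisq - df, chisq_b - df_b, .Machine$double.eps)
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1) {
    ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  } else NA_real_

  just_identified <- df == 0
  if (just_identified) {
    rmsea <- 0; rmsea_lo <- 0; rmsea_hi <- 0
  } else {
    rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
    ncp_root <- function(target_p) {
      f <- function(ncp) stats::pchisq(chisq, df, ncp = ncp) - target_p
      if (f(0) < 0) return(0)
      upper <- max(chisq * 2, df + 10)
      while (f(upper) > 0) upper <- upper * 2
      stats::uniroot(f, c(0, upper), tol = 1e-8)$root
    }
    rmsea_lo <- sqrt(ncp_root(0.95) / (df * (n - 1)))
    rmsea_hi <- sqrt(ncp_root(0.05) / (df * (n - 1)))
  }

  Dinv <- diag(1 / sqrt(diag(S)))
  resid <- Dinv %*% (S - fit$Sigma_hat) %*% Dinv
  srmr <- sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2))

  out <- data.frame(
    index = c("chisq", "df", "chisq_baseline", "df_baseline", "CFI", "TLI",
              "RMSEA", "RMSEA_lo90", "RMSEA_hi90", "SRMR"),
    value = c(chisq, df, chisq_b, df_b, cfi, tli,
              rmsea, rmsea_lo, rmsea_hi, srmr),
    stringsAsFactors = FALSE)
  attr(out, "just_identified") <- just_identified
  class(out) <- c("sem_fit_indices", "data.frame")
  out
}
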