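#' Simulate observed data from a structural equation model
#'
#' Draws exogenous latents from their covariance, forms endogenous latents
#' through the reduced structural form `eta = (I - beta)^{-1}(Gamma xi +
#' zeta)`, and adds unique measurement errors:
#' `x = Lambda_x xi + delta`, `y = Lambda_y eta + epsilon`. All draws are
#' multivariate normal with mean zero; covariance factors are computed by
#' eigendecomposition, so exactly-zero error variances (single-indicator
#' constructs) are handled. The sample covariance converges to
#' [implied_covariance()] as `n` grows.
#'
#' @param model a [build_model()] object.
#' @param params free-parameter vector or named list of full matrices (see
#'   [implied_covariance()]).
#' @param n sample size.
#' @param seed integer seed.
#' @return numeric matrix `n x p` with columns `model$obs_names`.
#' @export
generate_sem_sample <- function(model, params, n, seed = 1L) {
  stopifnot(inherits(model, "sem_model"), n >= 1)
  m <- .resolve_matrices(model, params)
  parts <- .implied_from_matrices(model, m)   # errors on singular (I - beta)
  ev <- eigen(parts$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("generate_sem_sample: implied covariance is not positive ",
         "semi-definite", call. = FALSE)
  }
  set.seed(as.integer(seed))
  nxi <- length(model$lat_xi); ne <- length(model$lat_eta)

  xi <- .rmvn_psd(n, m$Ph)
  if (ne > 0) {
    zeta <- .rmvn_psd(n, m$Ps)
    pred <- if (nxi > 0) xi %*% t(m$Ga) else matrix(0, n, ne)
    eta <- (pred + zeta) %*% t(parts$A)
  }
  X <- matrix(0, n, length(model$obs_names),
              dimnames = list(NULL, model$obs_names))
  if (length(model$obs_x)) {
    delta <- .rmvn_psd(n, m$Td)
    X[, model$obs_x] <- xi %*% t(m$Lx) + delta
  }
  if (length(model$obs_y)) {
    eps <- .rmvn_psd(n, m$Te)
    X[, model$obs_y] <- eta %*% t(m$Ly) + eps
  }
  X
}

# multivariate normal draw tolerating positive semi-definite covariance
.rmvn_psd <- function(n, Sigma) {
  k <- nrow(Sigma)
  if (k == 0) return(matrix(0, n, 0))
  eg <- eigen(Sigma, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  lam <- pmax(eg$values, 0)
  Z <- matrix(stats::rnorm(n * k), n, k)
  Z %*% (t(eg$vectors) * sqrt(lam))
}

#' Reference standardized parameterization of the structural preset
#'
#' The standardized coefficients used as ground truth when simulating from
#' the structural topology: loadings, structural paths, and the
#' variability / uterine-contraction latent correlation, all on the scale
#' where every latent and every observed variable has unit variance. The
#' values are the magnitudes characteristic of antepartum CTG data (strong
#' baseline-histogram loadings, an acceleration construct dominating the
#' fetal-status outcome, deceleration driven by uterine activity).
#'
#' @return list with `loadings` (named per latent), `paths` (data.frame
#'   from, to, coef), `latent_corr` (named value for the VCat-UCat pair).
#' @export
structural_reference_paths <- function() {
  list(
    loadings = list(
      VCat = c(Variance = -0.700, MSTV = -0.886, ALTV = 0.608,
               ASTV = 0.531, Width = -0.805),
      UCat = c(UC = 1.0),
      ACat = c(AC = 0.734, Nmax = 0.427, FM = 0.166),
      BCat = c(LB = 0.754, Mean = 0.975, Median = 0.992, Mode = 0.936),
      DCat = c(DP = 0.535, DL = 0.755, Nzeros = 0.345),
      FStat = c(NSP = 1.0)),
    paths = data.frame(
      from = c("VCat", "UCat", "ACat", "BCat", "DCat"),
      to   = c("BCat", "DCat", "FStat", "FStat", "FStat"),
      coef = c(0.527, 0.952, -0.665, -0.240, 0.173),
      stringsAsFactors = FALSE),
    latent_corr = c(VCat_UCat = -0.925))
}

#' Full generating matrices for the structural preset topology
#'
#' Converts the standardized parameterization of
#' [structural_reference_paths()] (or any same-shaped list) into full LISREL
#' matrices in the unit-variance-latent metric: loadings are the standardized
#' values, unique error variances are `1 - loading^2`, and structural
#' disturbance variances are solved recursively so that every endogenous
#' latent has unit variance. All observed variables then have unit variance
#' and the matrices can be fed to [generate_sem_sample()] or, through
#' [theta_from_matrices()], compared against a refit.
#'
#' @param model the [structural_model_preset()] (or a model with the same
#'   latents and paths).
#' @param std standardized parameterization, default
#'   [structural_reference_paths()].
#' @return named list of matrices `Lx`, `Ly`, `Be`, `Ga`, `Ph`, `Ps`, `Td`,
#'   `Te` matching the model's dimensions.
#' @export
structural_true_matrices <- function(model = structural_model_preset(),
                                     std = structural_reference_paths()) {
  mk <- function(tmpl) { m <- tmpl$value; m[is.na(m)] <- 0; m }
  Lx <- mk(model$Lx); Ly <- mk(model$Ly)
  Be <- mk(model$Be); Ga <- mk(model$Ga)
  Ph <- mk(model$Ph); Ps <- mk(model$Ps)
  Td <- mk(model$Td); Te <- mk(model$Te)

  for (L in model$lat_xi) {
    for (ind in names(std$loadings[[L]])) {
      Lx[ind, L] <- std$loadings[[L]][[ind]]
      Td[ind, ind] <- 1 - std$loadings[[L]][[ind]]^2
    }
    Ph[L, L] <- 1
  }
  for (L in model$lat_eta) {
    for (ind in names(std$loadings[[L]])) {
      Ly[ind, L] <- std$loadings[[L]][[ind]]
      Te[ind, ind] <- 1 - std$loadings[[L]][[ind]]^2
    }
  }
  for (i in seq_len(nrow(std$paths))) {
    f <- std$paths$from[i]; t <- std$paths$to[i]
    if (f %in% model$lat_xi) Ga[t, f] <- std$paths$coef[i]
    else Be[t, f] <- std$paths$coef[i]
  }
  Ph["VCat", "UCat"] <- Ph["UCat", "VCat"] <- std$latent_corr[["VCat_UCat"]]

  # disturbance variances giving every endogenous latent unit variance,
  # solved in topological order of the recursive system
  lat_all <- c(model$lat_xi, model$lat_eta)
  C <- matrix(0, length(lat_all), length(lat_all),
              dimnames = list(lat_all, lat_all))
  C[model$lat_xi, model$lat_xi] <- Ph
  remaining <- model$lat_eta
  done <- model$lat_xi
  while (length(remaining)) {
    progressed <- FALSE
    for (L in remaining) {
      preds <- c(model$lat_xi[Ga[L, ] != 0], model$lat_eta[Be[L, ] != 0])
      if (!all(preds %in% done)) next
      b <- stats::setNames(rep(0, length(lat_all)), lat_all)
      b[model$lat_xi] <- Ga[L, ]
      b[model$lat_eta] <- Be[L, ]
      expl <- as.numeric(t(b) %*% C %*% b)
      if (expl >= 1) {
        stop("structural_true_matrices: explained variance of '", L,
             "' is >= 1; standardized paths inconsistent", call. = FALSE)
      }
      Ps[L, L] <- 1 - expl
      C[L, L] <- 1
      for (M in done) {
        C[L, M] <- C[M, L] <- as.numeric(t(b) %*% C[, M])
      }
      done <- c(done, L)
      remaining <- setdiff(remaining, L)
      progressed <- TRUE
    }
    if (!progressed) {
      stop("structural_true_matrices: path system is not recursive",
           call. = FALSE)
    }
  }
  list(Lx = Lx, Ly = Ly, Be = Be, Ga = Ga, Ph = Ph, Ps = Ps,
       Td = Td, Te = Te)
}
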