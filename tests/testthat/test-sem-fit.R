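test_that("the ML discrepancy satisfies its defining identities", {
  set.seed(42)
  A <- matrix(rnorm(25), 5, 5)
  S <- crossprod(A) + diag(5)
  expect_equal(fml_discrepancy(S, S), 0)

  # scalar case evaluated by hand: S = I, Sigma = 2I, p = 2
  expect_equal(fml_discrepancy(diag(2), 2 * diag(2)), 2 * log(2) - 1)

  # dual-path check: eigenvalue form sum(l - log l) - p for l = eig(S Sig^-1)
  B <- matrix(rnorm(25), 5, 5)
  Sigma <- crossprod(B) + diag(5)
  l <- eigen(solve(Sigma) %*% S, only.values = TRUE)$values
  expect_equal(fml_discrepancy(S, Sigma),
               sum(Re(l) - log(Re(l))) - 5, tolerance = 1e-10)

  expect_error(fml_discrepancy(S, -Sigma), "positive definite")
})

test_that("noiseless data are refit to the generating parameters", {
  model <- two_factor_model()
  mats <- two_factor_true()
  theta_true <- theta_from_matrices(model, mats)
  Sigma <- implied_covariance(model, mats)
  fit <- fit_ml(model, sem_data(Sigma, n = 500, cov = TRUE))
  expect_true(fit$converged)
  expect_lt(fit$F_ML, 1e-10)
  expect_lt(max(abs(fit$theta - theta_true)), 1e-6)
})

test_that("the just-identified one-factor fit solves the moment equations", {
  model <- build_model(list(F1 = c("a", "b", "c")), scaling = c(F1 = "a"))
  # sample covariance from a noisy one-factor draw
  Lx <- matrix(c(1, 0.7, 1.4), 3, 1)
  X <- generate_sem_sample(model, list(Lx = Lx, Ph = matrix(2, 1, 1),
                                       Td = diag(c(0.5, 0.8, 0.4))),
                           n = 300, seed = 8)
  sdat <- sem_data(X)
  fit <- fit_ml(model, sdat)
  mats <- ctginterp:::.sem_matrices(model, fit$theta)
  lam <- mats$Lx[, 1]; phi <- mats$Ph[1, 1]
  S <- sdat$S
  expect_lt(abs(lam[1] * lam[2] * phi - S["a", "b"]), 1e-8)
  expect_lt(abs(lam[1] * lam[3] * phi - S["a", "c"]), 1e-8)
  expect_lt(abs(lam[2] * lam[3] * phi - S["b", "c"]), 1e-8)
  expect_lt(fit$F_ML, 1e-10)
})

test_that("fit_ml agrees with an independent optimizer on small models", {
  for (seed in 1:5) {
    set.seed(seed)
    model <- two_factor_model()
    mats <- two_factor_true()
    X <- generate_sem_sample(model, mats, n = 400, seed = 900 + seed)
    sdat <- sem_data(X)
    fit <- fit_ml(model, sdat, se = FALSE)

    S <- sdat$S[model$obs_names, model$obs_names]
    obj <- function(theta) {
      Sig <- tryCatch(implied_covariance(model, theta),
                      error = function(e) NULL)
      if (is.null(Sig)) return(1e10)
      tryCatch(fml_discrepancy(S, Sig), error = function(e) 1e10)
    }
    ind <- stats::optim(ctginterp:::.start_values(model, S), obj,
                        method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))
    expect_lt(abs(fit$F_ML - ind$value), 1e-7)
    expect_lt(max(abs(fit$theta - ind$par)), 1e-4)
  }
})

test_that("unstandardized loadings scale with the data, standardized do not", {
  model <- two_factor_model()
  X <- generate_sem_sample(model, two_factor_true(), n = 500, seed = 14)
  fit1 <- fit_ml(model, sem_data(X), se = FALSE)
  s1 <- standardize_solution(fit1)

  X2 <- X
  X2[, "v2"] <- 10 * X2[, "v2"]
  fit2 <- fit_ml(model, sem_data(X2), se = FALSE)
  s2 <- standardize_solution(fit2)

  raw1 <- s1$loadings$est[s1$loadings$indicator == "v2"]
  raw2 <- s2$loadings$est[s2$loadings$indicator == "v2"]
  expect_equal(raw2, 10 * raw1, tolerance = 1e-5)
  expect_equal(s2$loadings$est_std, s1$loadings$est_std, tolerance = 1e-7)
})

test_that("the positive-reference-loading convention fixes the latent sign", {
  # variance-scaled factor: the sign of the loadings is unidentified, so
  # the reported solution must have a positive first (reference-proxy) loading
  model <- build_model(list(F1 = c("a", "b", "c")), scaling = c(F1 = NA))
  Lx <- matrix(c(-0.9, -0.7, 0.5), 3, 1)
  X <- generate_sem_sample(model, list(Lx = Lx, Ph = matrix(1, 1, 1),
                                       Td = diag(c(0.3, 0.4, 0.5))),
                           n = 400, seed = 3)
  fit <- fit_ml(model, sem_data(X), se = FALSE)
  s <- standardize_solution(fit)
  expect_gt(s$loadings$est_std[s$loadings$indicator == "a"], 0)
  # b moves with a; c against: the flipped solution matches the generator
  # up to the global sign
  expect_gt(s$loadings$est_std[s$loadings$indicator == "b"], 0)
  expect_lt(s$loadings$est_std[s$loadings$indicator == "c"], 0)
})

test_that("Wald statistics follow their definitions", {
  model <- two_factor_model()
  X <- generate_sem_sample(model, two_factor_true(), n = 800, seed = 21)
  fit <- fit_ml(model, sem_data(X))
  w <- wald_statistics(fit)
  expect_equal(w$cr, w$estimate / w$se, tolerance = 1e-12)
  expect_equal(w$p, 2 * pnorm(-abs(w$cr)), tolerance = 1e-12)
  expect_true(all(w$sig[!is.na(w$p) & w$p < 0.001] == "***"))
  # reference loadings are fixed, hence absent from the table
  expect_false(any(grepl("Lx\\[v1,|Lx\\[v4,", w$label)))
  # a z of 1.96 corresponds to p of 0.05
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
})

test_that("effect decomposition obeys the product rule", {
  # chain xi -> eta1 (0.5 std) -> eta2 (0.4 std), no direct xi -> eta2
  latents <- list(X1 = c("x1", "x2"), E1 = c("y1", "y2"), E2 = c("z1", "z2"))
  paths <- data.frame(from = c("X1", "E1"), to = c("E1", "E2"))
  model <- build_model(latents, paths = paths,
                       scaling = c(X1 = "x1", E1 = "y1", E2 = "z1"))
  Lx <- matrix(c(1, 0.8), 2, 1)
  Ly <- matrix(0, 4, 2); Ly[1, 1] <- 1; Ly[2, 1] <- 0.9
  Ly[3, 2] <- 1; Ly[4, 2] <- 0.7
  Ga <- matrix(c(0.5, 0), 2, 1); Be <- matrix(0, 2, 2); Be[2, 1] <- 0.4
  mats <- list(Lx = Lx, Ly = Ly, Ga = Ga, Be = Be,
               Ph = matrix(1, 1, 1),
               Ps = diag(c(1 - 0.25, 1 - 0.16)),
               Td = diag(c(0.4, 0.4)), Te = diag(c(0.3, 0.3, 0.3, 0.3)))
  Sigma <- implied_covariance(model, mats)
  fit <- fit_ml(model, sem_data(Sigma, n = 1000, cov = TRUE), se = FALSE)
  eff <- effect_decomposition(fit, outcome = "E2")
  e <- eff$effects
  expect_equal(e$direct[e$source == "E1"], 0.4, tolerance = 1e-6)
  expect_equal(e$indirect[e$source == "E1"], 0, tolerance = 1e-8)
  expect_equal(e$direct[e$source == "X1"], 0, tolerance = 1e-8)
  expect_equal(e$indirect[e$source == "X1"], 0.5 * 0.4, tolerance = 1e-6)
  expect_equal(e$total[e$source == "X1"], 0.2, tolerance = 1e-6)
  ch <- eff$chains
  expect_equal(ch$product[ch$source == "X1" & ch$mediator == "E1"],
               0.2, tolerance = 1e-6)
})

test_that("fit indices are exact at a perfect fit and sane otherwise", {
  model <- two_factor_model()
  mats <- two_factor_true()
  Sigma <- implied_covariance(model, mats)
  fit <- fit_ml(model, sem_data(Sigma, n = 500, cov = TRUE), se = FALSE)
  fi <- fit_indices(fit)
  val <- function(k) fi$value[fi$index == k]
  expect_equal(val("chisq"), 0, tolerance = 1e-6)
  expect_equal(val("CFI"), 1, tolerance = 1e-8)
  expect_equal(val("RMSEA"), 0, tolerance = 1e-8)
  expect_lt(val("SRMR"), 1e-6)

  # noisy draw from the true model: indices should still look excellent
  X <- generate_sem_sample(model, mats, n = 2000, seed = 2)
  fit2 <- fit_ml(model, sem_data(X), se = FALSE)
  fi2 <- fit_indices(fit2)
  expect_gt(fi2$value[fi2$index == "CFI"], 0.97)
  expect_lt(fi2$value[fi2$index == "RMSEA"], 0.05)
  lo <- fi2$value[fi2$index == "RMSEA_lo90"]
  hi <- fi2$value[fi2$index == "RMSEA_hi90"]
  expect_lte(lo, fi2$value[fi2$index == "RMSEA"])
  expect_gte(hi, fi2$value[fi2$index == "RMSEA"])
})

test_that("a just-identified model reports RMSEA 0 with a flag", {
  model <- build_model(list(F1 = c("a", "b", "c")), scaling = c(F1 = "a"))
  X <- generate_sem_sample(model,
                           list(Lx = matrix(c(1, 0.8, 1.1), 3, 1),
                                Ph = matrix(1, 1, 1),
                                Td = diag(c(0.4, 0.4, 0.4))),
                           n = 200, seed = 6)
  fit <- fit_ml(model, sem_data(X), se = FALSE)
  fi <- fit_indices(fit)
  expect_true(attr(fi, "just_identified"))
  expect_equal(fi$value[fi$index == "RMSEA"], 0)
})

test_that("degenerate inputs raise informative errors", {
  model <- two_factor_model()
  X <- generate_sem_sample(model, two_factor_true(), n = 100, seed = 1)
  Xna <- X; Xna[1, 1] <- NA
  expect_error(sem_data(Xna), "missing values")
  S_bad <- diag(6) * 0
  colnames(S_bad) <- rownames(S_bad) <- model$obs_names
  expect_error(fit_ml(model, sem_data(S_bad, n = 100, cov = TRUE)),
               "positive definite")
})
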