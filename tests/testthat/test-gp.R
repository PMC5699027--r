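# kernel, marginal likelihood, penalized objective, fit and prediction

test_that("kernel matches closed forms and limits", {
  p <- list(sigma_f2 = 2, ell = 1.5, ell_s = 30)
  x <- c(0.3, -1); s <- c(10, 20)
  expect_equal(drop(gp_kernel(x, s, x, s, p)), 2)
  # feature distance with ||dx||^2 = 2 ell^2, same location -> sf2 * e^-1
  dx <- c(sqrt(2) * 1.5, 0)
  expect_equal(drop(gp_kernel(x, s, x + dx, s, p)), 2 * exp(-1),
               tolerance = 1e-12)
  # distance -> infinity
  expect_lt(drop(gp_kernel(x, s, x + 1e6, s, p)), 1e-12)
  # symmetry and bound on random pairs
  set.seed(1)
  X <- matrix(rnorm(12), 6, 2); S <- matrix(runif(12, 0, 50), 6, 2)
  K <- gp_kernel(X, S, X, S, p)
  expect_equal(K, t(K), tolerance = 1e-14)
  expect_true(all(K <= 2 + 1e-14) && all(K > 0))
  expect_error(gp_kernel(c(NA, 1), s, x, s, p))
})

test_that("marginal log likelihood matches scalar and density oracles", {
  # N = 1 closed form
  p <- list(beta = 0.7, ell = 1, ell_s = 10, sigma_f2 = 0.4, sigma_n2 = 0.2)
  y <- 1.3; x <- matrix(2, 1, 1); s <- matrix(c(5, 5), 1, 2)
  v <- 0.4 + 0.2
  expect_equal(gp_mll(y, x, s, p),
               -(y - 0.7 * 2)^2 / (2 * v) - 0.5 * log(v) - 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # N = 3: direct multivariate normal density (explicit inverse/determinant)
  set.seed(4)
  X <- matrix(rnorm(6), 3, 2); S <- matrix(runif(6, 0, 20), 3, 2)
  yv <- rnorm(3)
  p3 <- list(beta = c(0.5, -1), ell = 1.2, ell_s = 15,
             sigma_f2 = 0.8, sigma_n2 = 0.3)
  K <- gp_kernel(X, S, X, S, p3) + diag(0.3, 3)
  r <- yv - drop(X %*% p3$beta)
  dens <- -0.5 * drop(t(r) %*% solve(K) %*% r) -
    0.5 * log(det(K)) - 1.5 * log(2 * pi)
  expect_equal(gp_mll(yv, X, S, p3), dens, tolerance = 1e-8)
  # zero residual: only the determinant terms remain
  y0 <- drop(X %*% p3$beta)
  expect_equal(gp_mll(y0, X, S, p3),
               -0.5 * log(det(K)) - 1.5 * log(2 * pi), tolerance = 1e-8)
})

test_that("penalized objective applies the elastic net as printed", {
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2); S <- matrix(runif(20, 0, 30), 10, 2)
  y <- rnorm(10)
  p <- list(beta = c(1, -2), ell = 1, ell_s = 10, sigma_f2 = 0.5,
            sigma_n2 = 0.2)
  ll <- gp_mll(y, X, S, p)
  expect_equal(gp_objective(y, X, S, p, alpha = 0.5, lambda = 0), ll)
  # alpha = 1, lambda = 2, beta = (1, -2): penalty = 2 * (1 + 4) = 10
  expect_equal(gp_objective(y, X, S, p, alpha = 1, lambda = 2), ll - 10)
  p0 <- p; p0$beta <- c(0, 0)
  expect_equal(gp_penalty(p0$beta, alpha = 0.3, lambda = 5), 0)
})

test_that("posterior equals brute-force joint-Gaussian conditioning", {
  set.seed(11)
  for (rep in 1:10) {
    N <- sample(3:12, 1); d <- sample(1:4, 1)
    X <- matrix(rnorm(N * d), N, d)
    S <- matrix(runif(N * 2, 0, 100), N, 2)
    y <- rnorm(N)
    p <- list(beta = rnorm(d), ell = runif(1, 0.5, 3),
              ell_s = runif(1, 10, 80), sigma_f2 = runif(1, 0.1, 2),
              sigma_n2 = runif(1, 0.05, 0.5))
    model <- structure(list(
      beta = setNames(p$beta, paste0("x", 1:d)),
      ell = p$ell, ell_s = p$ell_s, sigma_f2 = p$sigma_f2,
      sigma_n2 = p$sigma_n2, source = "test",
      feature_names = paste0("x", 1:d),
      x_center = rep(0, d), x_scale = rep(1, d), y_center = 0,
      X = X, S = S, y = y,
      chol = chol(gp_kernel(X, S, X, S, p) + diag(p$sigma_n2, N)),
      n = N), class = "povgp")
    model$resid_weights <- backsolve(model$chol,
      backsolve(model$chol, y - drop(X %*% p$beta), transpose = TRUE))
    xs <- matrix(rnorm(d), 1, d); ss <- matrix(runif(2, 0, 100), 1, 2)
    pr <- predict(model, xs, ss)
    or <- gp_posterior_oracle(y, X, S, xs, ss, p)
    expect_equal(pr$mean, unname(or["mean"]), tolerance = 1e-8)
    expect_equal(pr$variance, unname(or["variance"]), tolerance = 1e-8)
  }
})

test_that("predictive variance respects its bounds and limits", {
  set.seed(21)
  N <- 20; d <- 3
  X <- matrix(rnorm(N * d), N, d, dimnames = list(NULL, paste0("x", 1:d)))
  S <- matrix(runif(N * 2, 0, 200), N, 2)
  y <- rnorm(N)
  fit <- gp_fit(X, S, y, lambda = 0.01, restarts = 1, maxit = 40, seed = 2)
  pr <- predict(fit, X, S)
  expect_true(all(pr$variance >= fit$sigma_n2 * (1 - 1e-6)))
  # far point: prior reversion to beta'x*, variance sf2 + sn2
  xs <- matrix(0, 1, d, dimnames = list(NULL, paste0("x", 1:d)))
  ss <- matrix(c(1e7, 1e7), 1, 2)
  far <- predict(fit, xs, ss)
  mu_far <- fit$y_center +
    drop(scale(xs, fit$x_center, fit$x_scale) %*% fit$beta)
  expect_equal(far$mean, mu_far, tolerance = 1e-8)
  expect_equal(far$variance, fit$sigma_f2 + fit$sigma_n2, tolerance = 1e-8)
  # variance is unchanged when all targets are replaced
  fit2 <- fit
  ynew <- rnorm(N)
  fit2$y <- ynew - mean(ynew); fit2$y_center <- mean(ynew)
  fit2$resid_weights <- backsolve(fit2$chol,
    backsolve(fit2$chol, fit2$y - drop(fit2$X %*% fit2$beta),
              transpose = TRUE))
  expect_equal(predict(fit2, X, S)$variance, pr$variance, tolerance = 1e-12)
})

test_that("adding a training point never inflates predictive variance", {
  set.seed(31)
  N <- 15; d <- 2
  X <- matrix(rnorm((N + 1) * d), N + 1, d)
  S <- matrix(runif((N + 1) * 2, 0, 100), N + 1, 2)
  y <- rnorm(N + 1)
  p <- list(beta = c(0.4, -0.2), ell = 1.5, ell_s = 40,
            sigma_f2 = 1, sigma_n2 = 0.2)
  mk <- function(idx) {
    K <- gp_kernel(X[idx, ], S[idx, ], X[idx, ], S[idx, ], p)
    U <- chol(K + diag(p$sigma_n2, length(idx)))
    m <- structure(list(beta = p$beta, ell = p$ell, ell_s = p$ell_s,
                        sigma_f2 = p$sigma_f2, sigma_n2 = p$sigma_n2,
                        source = "t", feature_names = NULL,
                        x_center = rep(0, d), x_scale = rep(1, d),
                        y_center = 0, X = X[idx, ], S = S[idx, ],
                        y = y[idx], chol = U, n = length(idx)),
                   class = "povgp")
    m$resid_weights <- backsolve(U, backsolve(U,
      y[idx] - drop(X[idx, ] %*% p$beta), transpose = TRUE))
    m
  }
  xs <- matrix(rnorm(d), 1, d); ss <- matrix(runif(2, 0, 100), 1, 2)
  v_small <- predict(mk(1:N), xs, ss)$variance
  v_big <- predict(mk(1:(N + 1)), xs, ss)$variance
  expect_lte(v_big, v_small + 1e-10)
})

test_that("noise-free interpolation reproduces training targets", {
  set.seed(41)
  N <- 12; d <- 2
  X <- matrix(rnorm(N * d), N, d)
  S <- matrix(runif(N * 2, 0, 50), N, 2)
  y <- rnorm(N)
  p <- list(beta = c(0, 0), ell = 2, ell_s = 30, sigma_f2 = 1,
            sigma_n2 = 1e-10)
  U <- chol(gp_kernel(X, S, X, S, p) + diag(p$sigma_n2 + 1e-12, N))
  m <- structure(list(beta = p$beta, ell = p$ell, ell_s = p$ell_s,
                      sigma_f2 = p$sigma_f2, sigma_n2 = p$sigma_n2,
                      source = "t", feature_names = NULL,
                      x_center = rep(0, d), x_scale = rep(1, d),
                      y_center = 0, X = X, S = S, y = y, chol = U, n = N),
                 class = "povgp")
  m$resid_weights <- backsolve(U, backsolve(U, y, transpose = TRUE))
  pr <- predict(m, X, S)
  expect_equal(pr$mean, y, tolerance = 1e-5)
  expect_true(all(pr$variance < 1e-6))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(51)
  N <- 12; d <- 3
  X <- matrix(rnorm(N * d), N, d)
  S <- matrix(runif(N * 2, 0, 60), N, 2)
  y <- rnorm(N)
  ob <- povgp:::make_negobj(y, X, povgp:::sq_dist(X), povgp:::sq_dist(S),
                            alpha = 0.4, lambda = 0.3)
  par <- c(rnorm(d) * 0.5, log(1.5), log(30), log(0.7), log(0.2))
  g <- ob$gr(par)
  h <- 1e-5
  gfd <- vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- h
    (ob$fn(par + e) - ob$fn(par - e)) / (2 * h)
  }, numeric(1))
  expect_equal(g, gfd, tolerance = 1e-5)
})

test_that("with no GP term the fit matches a penalized least-squares solve", {
  cfg <- synthetic_config(n_communes = 200, n_urban = 40, n_regions = 8,
                          map_extent_km = 400, seed = 6,
                          kernel = list(sigma_f2 = 0, ell = 3, ell_s = 50,
                                        sigma_n2 = 0.1))
  map <- generate_commune_map(cfg)
  fld <- generate_latent_field(map, cfg, source = "env")
  fit <- gp_fit(fld$X, fld$S, fld$y, alpha = 1, lambda = 0.5,
                restarts = 2, seed = 3)
  # alpha = 1 is a pure (scaled) ridge penalty: the stationarity condition
  # of J at fixed variance gives beta = (X'X + 2 lambda v I)^-1 X'y on the
  # standardized design, with v the fitted residual variance
  Xs <- scale(fld$X)
  ys <- fld$y - mean(fld$y)
  v <- fit$sigma_n2 + fit$sigma_f2
  beta_ridge <- drop(solve(crossprod(Xs) + diag(2 * 0.5 * v, ncol(Xs)),
                           crossprod(Xs, ys)))
  # compare only the informative coefficients (relative error <= 10%)
  big <- abs(beta_ridge) > 0.2
  expect_true(all(abs(coef(fit)[big] - beta_ridge[big]) /
                    abs(beta_ridge[big]) < 0.1))
})

test_that("length-scale and support recovery on a seeded full-model draw", {
  cfg <- synthetic_config(n_communes = 300, n_urban = 66, n_regions = 14,
                          seed = 11)
  map <- generate_commune_map(cfg)
  fld <- generate_latent_field(map, cfg, source = "cdr")
  fit <- gp_fit(fld$X, fld$S, fld$y, lambda = 0.05, restarts = 3, seed = 2)
  expect_gt(fit$ell_s, 25)   # true 50 km, factor-2 band
  expect_lt(fit$ell_s, 100)
  est_support <- abs(coef(fit)) >= 0.1
  true_support <- fld$beta_true != 0
  expect_equal(est_support, setNames(true_support, names(coef(fit))))
})

test_that("duplicating every training point does not raise fitted noise", {
  cfg <- synthetic_config(n_communes = 80, n_urban = 16, n_regions = 4,
                          map_extent_km = 300, seed = 17)
  map <- generate_commune_map(cfg)
  fld <- generate_latent_field(map, cfg)
  fit1 <- gp_fit(fld$X, fld$S, fld$y, lambda = 0.05, restarts = 1,
                 maxit = 80, seed = 4)
  fit2 <- gp_fit(rbind(fld$X, fld$X), rbind(fld$S, fld$S),
                 c(fld$y, fld$y), lambda = 0.05, restarts = 1,
                 maxit = 80, seed = 4)
  expect_lte(fit2$sigma_n2, fit1$sigma_n2 * 1.05)
})

test_that("large penalties shrink the coefficient norm monotonically", {
  cfg <- synthetic_config(n_communes = 100, n_urban = 20, n_regions = 5,
                          map_extent_km = 300, seed = 23)
  map <- generate_commune_map(cfg)
  fld <- generate_latent_field(map, cfg)
  norms <- vapply(c(0.01, 1, 100), function(lam) {
    # huge penalties legitimately hit maxit while grinding beta to zero;
    # the fit warns (never silent) and returns the best iterate
    fit <- suppressWarnings(gp_fit(fld$X, fld$S, fld$y, lambda = lam,
                                   restarts = 1, maxit = 80, seed = 5))
    sqrt(sum(coef(fit)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 0.05)
})

test_that("feature importance ranks by magnitude and flags pruned", {
  m <- structure(list(beta = c(a = 0.2, b = -1.5, c = 0)), class = "povgp")
  imp <- feature_importance(m)
  expect_equal(imp$feature, c("b", "a", "c"))
  expect_equal(imp$pruned, c(FALSE, FALSE, TRUE))
  # permutation equivariance
  m2 <- structure(list(beta = c(c = 0, b = -1.5, a = 0.2)), class = "povgp")
  imp2 <- feature_importance(m2)
  expect_equal(imp2$feature, imp$feature)
  # all-zero coefficients: everything pruned
  m0 <- structure(list(beta = c(a = 0, b = 0)), class = "povgp")
  expect_true(all(feature_importance(m0)$pruned))
})

test_that("prediction errors on mismatched feature schema", {
  set.seed(61)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  S <- matrix(runif(40, 0, 50), 20, 2)
  fit <- gp_fit(X, S, rnorm(20), lambda = 0.1, restarts = 1, maxit = 30,
                seed = 6)
  bad <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("f1", "zz")))
  expect_error(predict(fit, bad, S[1:2, ]), "zz")
})

test_that("model JSON round-trip preserves predictions", {
  set.seed(71)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("f1", "f2")))
  S <- matrix(runif(60, 0, 80), 30, 2)
  y <- rnorm(30)
  fit <- gp_fit(X, S, y, lambda = 0.1, restarts = 1, maxit = 40, seed = 7)
  path <- tempfile(fileext = ".json")
  gp_save(fit, path)
  back <- gp_load(path)
  Xn <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
  Sn <- matrix(runif(10, 0, 80), 5, 2)
  expect_equal(predict(back, Xn, Sn)$mean, predict(fit, Xn, Sn)$mean,
               tolerance = 1e-10)
  expect_equal(predict(back, Xn, Sn)$variance,
               predict(fit, Xn, Sn)$variance, tolerance = 1e-10)
})

test_that("inner cross-validation selects a penalty from the grid", {
  set.seed(2)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  S <- matrix(runif(n * 2, 0, 100), n, 2)
  y <- drop(X %*% c(1, -0.5, 0)) + rnorm(n, 0, 0.3)
  fit <- gp_fit(X, S, y, lambda = NULL, restarts = 1, maxit = 60, seed = 3)
  expect_true(fit$lambda %in% 10^seq(-2, 1, length.out = 5))
  # informative coefficients survive the selected penalty
  expect_gt(abs(coef(fit)["f1"]), 0.5)
})
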