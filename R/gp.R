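# Gaussian-process regression with a product feature x spatial squared
# exponential kernel and an elastic-net-penalized linear mean.
#
# Model: y_i = beta' x_i + f(x_i, s_i) + eps_i,  eps_i ~ N(0, sigma_n2),
# f ~ GP(0, k) with
#   k((x,s),(x',s')) = sigma_f2 exp(-||x-x'||^2 / (2 l^2))
#                               exp(-||s-s'||^2 / (2 l_s^2)).
# Hyperparameters are estimated by maximizing the penalized marginal
# likelihood J = log p(y|X) - (alpha lambda ||beta||_2^2
#                              + (1-alpha) lambda ||beta||_1).

# squared Euclidean distance matrix between rows of A and rows of B
sq_dist <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Product feature-by-spatial squared exponential kernel
#'
#' Covariance between points given by feature vectors and planar spatial
#' coordinates (km): `sigma_f2 * exp(-||x-x'||^2/(2 ell^2)) *
#' exp(-||s-s'||^2/(2 ell_s^2))`.
#'
#' @param X1,X2 feature matrices (rows are points; a single point may be a
#'   vector).
#' @param S1,S2 spatial coordinate matrices (two columns, km).
#' @param params list with `sigma_f2`, `ell`, `ell_s`.
#' @return covariance matrix `nrow(X1)` x `nrow(X2)`.
#' @export
gp_kernel <- function(X1, S1, X2 = X1, S2 = S1, params) {
  if (is.null(dim(X1))) X1 <- matrix(X1, nrow = 1)
  if (is.null(dim(X2))) X2 <- matrix(X2, nrow = 1)
  if (is.null(dim(S1))) S1 <- matrix(S1, nrow = 1)
  if (is.null(dim(S2))) S2 <- matrix(S2, nrow = 1)
  stopifnot(all(is.finite(X1)), all(is.finite(X2)),
            all(is.finite(S1)), all(is.finite(S2)),
            params$ell > 0, params$ell_s > 0, params$sigma_f2 >= 0)
  Df <- sq_dist(X1, X2)
  Ds <- sq_dist(S1, S2)
  params$sigma_f2 * exp(-Df / (2 * params$ell^2) - Ds / (2 * params$ell_s^2))
}

# Cholesky with an escalating jitter on the diagonal (1e-8 .. 1e-4 of the
# mean diagonal). Returns the upper-triangular factor.
chol_jitter <- function(Q) {
  d <- mean(diag(Q))
  for (j in c(0, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4)) {
    U <- tryCatch(chol(Q + diag(j * max(d, 1), nrow(Q))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  stop("covariance factorization failed after maximal jitter; ",
       "check sigma_n2/sigma_f2 settings")
}

#' Marginal log likelihood of the GP regression model
#'
#' `-1/2 (y-Xb)'(K+sn2 I)^-1 (y-Xb) - 1/2 log|K+sn2 I| - N/2 log 2pi`,
#' computed through a Cholesky factorization (never an explicit inverse).
#'
#' @param y numeric targets.
#' @param X feature matrix (N x d).
#' @param S spatial coordinates (N x 2, km).
#' @param params list with `beta`, `ell`, `ell_s`, `sigma_f2`, `sigma_n2`.
#' @return scalar log likelihood.
#' @export
gp_mll <- function(y, X, S, params) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, params$sigma_n2 > 0)
  K <- gp_kernel(X, S, X, S, params)
  Q <- K + diag(params$sigma_n2, n)
  U <- chol_jitter(Q)
  r <- y - drop(X %*% params$beta)
  w <- backsolve(U, r, transpose = TRUE)
  -0.5 * sum(w^2) - sum(log(diag(U))) - n / 2 * log(2 * pi)
}

#' Elastic-net penalty on the linear coefficients
#'
#' `alpha * lambda * ||beta||_2^2 + (1 - alpha) * lambda * ||beta||_1`
#' (the L2 term carries `alpha`, the L1 term `1 - alpha`).
#'
#' @param beta coefficient vector.
#' @param alpha mixing weight in \[0, 1\].
#' @param lambda penalty strength >= 0.
#' @return scalar penalty.
#' @export
gp_penalty <- function(beta, alpha, lambda) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  alpha * lambda * sum(beta^2) + (1 - alpha) * lambda * sum(abs(beta))
}

#' Penalized marginal likelihood objective J
#'
#' Marginal log likelihood minus the elastic-net penalty on `beta`
#' (kernel hyperparameters are unpenalized).
#'
#' @inheritParams gp_mll
#' @param alpha,lambda penalty settings, see [gp_penalty()].
#' @return scalar objective (to be maximized).
#' @export
gp_objective <- function(y, X, S, params, alpha = 0.5, lambda = 0) {
  gp_mll(y, X, S, params) - gp_penalty(params$beta, alpha, lambda)
}

# internal smoothed objective/gradient on the optimizer's parameter scale:
# par = c(beta, log ell, log ell_s, log sigma_f2, log sigma_n2).
# |beta| is smoothed as sqrt(beta^2 + eps^2) so that gradient methods apply.
make_negobj <- function(y, X, D2f, D2s, alpha, lambda, smooth_eps = 1e-8) {
  n <- length(y); d <- ncol(X)
  unpack <- function(par) {
    par <- unname(par)
    list(beta = par[seq_len(d)],
         ell = exp(par[d + 1]), ell_s = exp(par[d + 2]),
         sigma_f2 = exp(par[d + 3]), sigma_n2 = exp(par[d + 4]))
  }
  shared <- function(par) {
    p <- unpack(par)
    K <- p$sigma_f2 * exp(-D2f / (2 * p$ell^2) - D2s / (2 * p$ell_s^2))
    Q <- K + diag(p$sigma_n2, n)
    U <- chol_jitter(Q)
    r <- y - drop(X %*% p$beta)
    a <- backsolve(U, backsolve(U, r, transpose = TRUE))
    list(p = p, K = K, U = U, r = r, a = a)
  }
  fn <- function(par) {
    s <- shared(par)
    mll <- -0.5 * sum(s$r * s$a) - sum(log(diag(s$U))) - n / 2 * log(2 * pi)
    pen <- alpha * lambda * sum(s$p$beta^2) +
      (1 - alpha) * lambda * sum(sqrt(s$p$beta^2 + smooth_eps^2))
    -(mll - pen)
  }
  gr <- function(par) {
    s <- shared(par)
    p <- s$p
    Qinv <- chol2inv(s$U)
    M <- tcrossprod(s$a) - Qinv
    gbeta <- drop(crossprod(X, s$a)) -
      (2 * alpha * lambda * p$beta +
         (1 - alpha) * lambda * p$beta / sqrt(p$beta^2 + smooth_eps^2))
    g_ell   <- 0.5 * sum(M * (s$K * D2f / p$ell^2))
    g_ells  <- 0.5 * sum(M * (s$K * D2s / p$ell_s^2))
    g_sf2   <- 0.5 * sum(M * s$K)
    g_sn2   <- 0.5 * p$sigma_n2 * sum(diag(M))
    -c(gbeta, g_ell, g_ells, g_sf2, g_sn2)
  }
  list(fn = fn, gr = gr, unpack = unpack)
}

#' Fit the penalized Gaussian-process regression model
#'
#' Maximizes the penalized marginal likelihood J over the linear
#' coefficients and the kernel hyperparameters (the latter on log scale)
#' with a gradient-based optimizer and multiple seeded restarts. Features
#' are standardized to zero mean and unit standard deviation (so that a
#' single shared feature length-scale is meaningful) and the target is
#' centred; both transformations are stored and undone at prediction time.
#'
#' @param X N x d feature matrix (column names become feature names).
#' @param coords N x 2 matrix of planar spatial coordinates in km.
#' @param y numeric target vector (e.g. commune MPI).
#' @param alpha elastic-net mixing weight in \[0, 1\] (L2 share).
#' @param lambda penalty strength; `NULL` selects it by inner
#'   `cv_folds`-fold cross-validation over `lambda_grid`.
#' @param lambda_grid candidate penalties for the inner selection.
#' @param cv_folds folds for the inner lambda selection.
#' @param restarts number of optimizer restarts with perturbed length-scale
#'   initializations.
#' @param method `optim` method; `"BFGS"` (default) or `"CG"`, both use the
#'   analytic gradient.
#' @param maxit maximum optimizer iterations per restart.
#' @param source label attached to predictions (e.g. `"cdr"`, `"env"`).
#' @param seed integer seed for the restart perturbations.
#' @return object of class `"povgp"` with coefficients, kernel
#'   hyperparameters, standardization parameters, cached training matrices
#'   and a convergence log. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`, `logLik`.
#' @export
gp_fit <- function(X, coords, y, alpha = 0.5, lambda = 0.1,
                   lambda_grid = 10^seq(-2, 1, length.out = 5),
                   cv_folds = 5, restarts = 3, method = "BFGS",
                   maxit = 150, source = "source", seed = 1L) {
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  n <- length(y); d <- ncol(X)
  stopifnot(nrow(X) == n, nrow(coords) == n, ncol(coords) == 2,
            all(is.finite(X)), all(is.finite(y)), all(is.finite(coords)))
  if (n < 10) stop("need at least 10 training communes")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(d))

  if (is.null(lambda)) {
    lambda <- select_lambda_cv(X, coords, y, alpha, lambda_grid, cv_folds,
                               method = method, seed = seed)
  }

  xc <- colMeans(X); xs <- apply(X, 2, stats::sd)
  xs[xs < 1e-12] <- 1
  Xs <- scale(X, center = xc, scale = xs)
  yc <- mean(y); ys <- y - yc

  D2f <- sq_dist(Xs)
  D2s <- sq_dist(coords)
  ob <- make_negobj(ys, Xs, D2f, D2s, alpha, lambda)

  # data-driven initialization: ridge beta, median-distance length-scales,
  # residual variance split between signal and noise
  beta0 <- drop(solve(crossprod(Xs) + diag(1, d), crossprod(Xs, ys)))
  r0 <- ys - drop(Xs %*% beta0)
  v0 <- max(stats::var(r0), 1e-6)
  ell0 <- sqrt(max(stats::median(D2f[upper.tri(D2f)]), 1e-4))
  ells0 <- sqrt(max(stats::median(D2s[upper.tri(D2s)]), 1e-4))
  base <- c(beta0, log(ell0), log(ells0), log(v0 / 2), log(v0 / 2))

  fits <- with_seed(as.integer(seed), {
    lapply(seq_len(restarts), function(r) {
      par0 <- base
      if (r > 1) {
        # perturb length-scales across orders of magnitude; keep beta init
        par0[d + 1] <- base[d + 1] + stats::runif(1, -2, 1)
        par0[d + 2] <- base[d + 2] + stats::runif(1, -3, 0.7)
        par0[d + 3] <- base[d + 3] + stats::runif(1, -1, 1)
      }
      f0 <- ob$fn(par0)
      res <- tryCatch(
        stats::optim(par0, ob$fn, ob$gr, method = method,
                     control = list(maxit = maxit)),
        error = function(e) list(par = par0, value = f0, convergence = 99L))
      if (!is.finite(res$value) || res$value > f0) {
        res$par <- par0; res$value <- f0; res$convergence <- 98L
      }
      res
    })
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  if (all(vapply(fits, `[[`, integer(1), "convergence") != 0L))
    warning("optimizer did not report convergence in any restart; ",
            "returning the best iterate")
  p <- ob$unpack(best$par)
  names(p$beta) <- colnames(X)

  # cache posterior quantities for prediction
  K <- p$sigma_f2 * exp(-D2f / (2 * p$ell^2) - D2s / (2 * p$ell_s^2))
  U <- chol_jitter(K + diag(p$sigma_n2, n))
  r <- ys - drop(Xs %*% p$beta)
  a <- backsolve(U, backsolve(U, r, transpose = TRUE))

  structure(list(
    beta = p$beta, ell = p$ell, ell_s = p$ell_s,
    sigma_f2 = p$sigma_f2, sigma_n2 = p$sigma_n2,
    alpha = alpha, lambda = lambda, source = source,
    feature_names = colnames(X),
    x_center = xc, x_scale = xs, y_center = yc,
    X = Xs, S = coords, y = ys, chol = U, resid_weights = a,
    objective = -best$value,
    mll = gp_mll(ys, Xs, coords, p),
    convergence = vapply(fits, `[[`, integer(1), "convergence"),
    n = n, call = match.call()
  ), class = "povgp")
}

# inner K-fold CV over a lambda grid (squared error of the posterior mean)
select_lambda_cv <- function(X, coords, y, alpha, lambda_grid, cv_folds,
                             method, seed) {
  n <- length(y)
  folds <- with_seed(as.integer(seed) + 7L,
                     sample(rep(seq_len(cv_folds), length.out = n)))
  errs <- vapply(lambda_grid, function(lam) {
    se <- 0
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      if (sum(tr) < 10 || sum(!tr) < 1) next
      # short-leash probe fits; their convergence flags are irrelevant
      fit <- suppressWarnings(
        gp_fit(X[tr, , drop = FALSE], coords[tr, , drop = FALSE], y[tr],
               alpha = alpha, lambda = lam, restarts = 1,
               method = method, maxit = 60, seed = seed))
      pr <- predict(fit, X[!tr, , drop = FALSE], coords[!tr, , drop = FALSE])
      se <- se + sum((pr$mean - y[!tr])^2)
    }
    se
  }, numeric(1))
  lambda_grid[which.min(errs)]
}

#' Posterior prediction for new communes
#'
#' Posterior mean `beta' x* + k' (K + sn2 I)^-1 (y - X beta)` and variance
#' `k* - k' (K + sn2 I)^-1 k + sn2`. The variance depends only on the
#' inputs, never on the observed targets.
#'
#' @param object fitted `"povgp"` model.
#' @param X feature matrix for the new communes; if it has column names
#'   they must match the training features (a mismatch is an error).
#' @param coords spatial coordinates (km) of the new communes.
#' @param ... unused.
#' @return data.frame with columns `mean`, `variance`, `source` (row names
#'   carried over from `X`).
#' @export
predict.povgp <- function(object, X, coords, ...) {
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  if (!is.null(colnames(X))) {
    if (!identical(colnames(X), object$feature_names)) {
      miss <- setdiff(object$feature_names, colnames(X))
      extra <- setdiff(colnames(X), object$feature_names)
      if (length(miss) || length(extra))
        stop("feature columns do not match training features; missing: ",
             paste(miss, collapse = ", "), "; unknown: ",
             paste(extra, collapse = ", "))
      X <- X[, object$feature_names, drop = FALSE]
    }
  }
  stopifnot(ncol(X) == length(object$beta), nrow(coords) == nrow(X))
  Xs <- scale(X, center = object$x_center, scale = object$x_scale)
  params <- list(sigma_f2 = object$sigma_f2, ell = object$ell,
                 ell_s = object$ell_s)
  kx <- gp_kernel(Xs, coords, object$X, object$S, params)  # m x n
  mu <- object$y_center + drop(Xs %*% object$beta) +
    drop(kx %*% object$resid_weights)
  w <- backsolve(object$chol, t(kx), transpose = TRUE)     # n x m
  v <- object$sigma_f2 - colSums(w^2) + object$sigma_n2
  v <- pmax(v, object$sigma_n2 * (1 - 1e-9))
  out <- data.frame(mean = mu, variance = v,
                    source = object$source,
                    row.names = rownames(X), stringsAsFactors = FALSE)
  out
}

#' @export
coef.povgp <- function(object, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") return(object$beta)
  object$beta / object$x_scale
}

#' @export
fitted.povgp <- function(object, ...) {
  pr <- predict(object, unscale_X(object), object$S)
  pr$mean
}

unscale_X <- function(object) {
  sweep(sweep(object$X, 2, object$x_scale, "*"), 2, object$x_center, "+")
}

#' @export
residuals.povgp <- function(object, ...) {
  (object$y + object$y_center) - fitted(object)
}

#' @export
logLik.povgp <- function(object, ...) {
  structure(object$mll, df = length(object$beta) + 4, class = "logLik")
}

#' Simulate from the posterior predictive distribution
#'
#' Draws independent normal deviates from the per-commune posterior
#' predictive at new inputs (or the training inputs by default).
#'
#' @param object fitted `"povgp"` model.
#' @param nsim number of simulated replicates.
#' @param seed optional integer seed.
#' @param X,coords optional new inputs; defaults to the training data.
#' @param ... unused.
#' @return matrix with one column per replicate.
#' @export
simulate.povgp <- function(object, nsim = 1, seed = NULL,
                           X = NULL, coords = NULL, ...) {
  if (is.null(X)) { X <- unscale_X(object); coords <- object$S }
  pr <- predict(object, X, coords)
  draw <- function() stats::rnorm(nrow(pr), pr$mean, sqrt(pr$variance))
  if (!is.null(seed)) {
    with_seed(as.integer(seed), matrix(replicate(nsim, draw()), ncol = nsim))
  } else {
    matrix(replicate(nsim, draw()), ncol = nsim)
  }
}

#' @export
print.povgp <- function(x, ...) {
  cat("Gaussian-process small-area model (source: ", x$source, ")\n", sep = "")
  cat(sprintf("  n = %d communes, %d features\n", x$n, length(x$beta)))
  cat(sprintf("  ell = %.3g  ell_s = %.3g km  sigma_f2 = %.3g  sigma_n2 = %.3g\n",
              x$ell, x$ell_s, x$sigma_f2, x$sigma_n2))
  cat(sprintf("  elastic net: alpha = %.2f, lambda = %.3g\n", x$alpha, x$lambda))
  cat(sprintf("  penalized marginal log likelihood J = %.4f\n", x$objective))
  invisible(x)
}

#' @export
summary.povgp <- function(object, ...) {
  imp <- feature_importance(object)
  res <- residuals(object)
  structure(list(model = object, importance = imp,
                 resid_summary = summary(res),
                 rmse_train = sqrt(mean(res^2))),
            class = "summary.povgp")
}

#' @export
print.summary.povgp <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training RMSE: %.4f\n", x$rmse_train))
  cat("\nFeatures ranked by |beta| (standardized scale):\n")
  print(x$importance, row.names = FALSE)
  invisible(x)
}

#' Observed-versus-fitted plot with predictive uncertainty
#'
#' @param x fitted `"povgp"` model.
#' @param ... passed to `plot`.
#' @export
plot.povgp <- function(x, ...) {
  pr <- predict(x, unscale_X(x), x$S)
  obs <- x$y + x$y_center
  graphics::plot(obs, pr$mean, xlab = "observed", ylab = "posterior mean",
                 main = paste0("povgp fit (", x$source, ")"),
                 cex = 0.3 + 2 * sqrt(pr$variance) / max(sqrt(pr$variance)),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Rank features by coefficient magnitude
#'
#' Features are sorted by `|beta|` (standardized scale) in decreasing
#' order; entries with `|beta|` below `prune_tol` are flagged as pruned by
#' the elastic net.
#'
#' @param object fitted `"povgp"` model.
#' @param prune_tol magnitude below which a coefficient counts as zero.
#' @return data.frame with columns `feature`, `beta`, `magnitude`, `rank`,
#'   `pruned`.
#' @export
feature_importance <- function(object, prune_tol = 1e-4) {
  b <- object$beta
  ord <- order(abs(b), decreasing = TRUE)
  data.frame(feature = names(b)[ord],
             beta = unname(b[ord]),
             magnitude = unname(abs(b[ord])),
             rank = seq_along(b),
             pruned = unname(abs(b[ord]) < prune_tol),
             stringsAsFactors = FALSE)
}

#' Serialize a fitted model to JSON
#'
#' Stores hyperparameters, standardization parameters, feature names and a
#' checksum-free copy of the training inputs so the model can be reloaded
#' and used for prediction.
#'
#' @param object fitted `"povgp"` model.
#' @param path output file.
#' @export
gp_save <- function(object, path) {
  doc <- list(
    class = "povgp",
    source = object$source,
    beta = as.list(object$beta),
    ell = object$ell, ell_s = object$ell_s,
    sigma_f2 = object$sigma_f2, sigma_n2 = object$sigma_n2,
    alpha = object$alpha, lambda = object$lambda,
    x_center = as.list(object$x_center), x_scale = as.list(object$x_scale),
    y_center = object$y_center,
    X = unclass(object$X), S = object$S, y = object$y
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a model written by [gp_save()]
#' @param path JSON file.
#' @return object of class `"povgp"`.
#' @export
gp_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- as.matrix(doc$X); S <- as.matrix(doc$S)
  beta <- unlist(doc$beta)
  obj <- list(beta = beta, ell = doc$ell, ell_s = doc$ell_s,
              sigma_f2 = doc$sigma_f2, sigma_n2 = doc$sigma_n2,
              alpha = doc$alpha, lambda = doc$lambda, source = doc$source,
              feature_names = names(beta),
              x_center = unlist(doc$x_center), x_scale = unlist(doc$x_scale),
              y_center = doc$y_center,
              X = X, S = S, y = doc$y, n = nrow(X))
  colnames(obj$X) <- obj$feature_names
  params <- list(sigma_f2 = obj$sigma_f2, ell = obj$ell, ell_s = obj$ell_s)
  K <- gp_kernel(X, S, X, S, params)
  obj$chol <- chol_jitter(K + diag(obj$sigma_n2, nrow(X)))
  r <- doc$y - drop(X %*% beta)
  obj$resid_weights <- backsolve(obj$chol,
                                 backsolve(obj$chol, r, transpose = TRUE))
  obj$mll <- gp_mll(doc$y, X, S,
                    c(params, list(beta = beta, sigma_n2 = obj$sigma_n2)))
  obj$objective <- obj$mll - gp_penalty(beta, obj$alpha, obj$lambda)
  obj$convergence <- NA_integer_
  structure(obj, class = "povgp")
}
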