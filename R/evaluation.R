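# Validation harness: distance-buffered spatial cross-validation, standard
# repeated k-fold CV, metric computation (Pearson, Spearman, RMSE with SDs
# over repeats) and the four-feature linear baseline.

#' Spatial cross-validation settings
#'
#' The splitter samples a region, then a commune within it, and grows a
#' radius from `d_init` in steps of `d_step` until the training set (all
#' communes within the radius of the seed commune) reaches
#' `min_train_size`; the remaining communes form the evaluation set. The
#' default floor is the absolute 225 at the 552-commune map size and
#' `ceiling(0.4 n)` otherwise.
#'
#' @param d_init initial radius, km.
#' @param d_step radius increment, km.
#' @param min_train_size training-set floor in communes (NULL = default
#'   rule).
#' @param n_repeats number of repeated splits.
#' @param seed integer seed for the repeat stream.
#' @return classed list `"spatial_cv_config"`.
#' @export
spatial_cv_config <- function(d_init = 100, d_step = 50,
                              min_train_size = NULL, n_repeats = 250,
                              seed = 1L) {
  stopifnot(d_init > 0, d_step > 0, n_repeats >= 1)
  structure(list(d_init = d_init, d_step = d_step,
                 min_train_size = min_train_size,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "spatial_cv_config")
}

min_train_default <- function(n_communes) {
  if (n_communes == 552L) 225L else as.integer(ceiling(0.4 * n_communes))
}

#' One spatial cross-validation split
#'
#' @param map a `"commune_map"`.
#' @param config a [spatial_cv_config()].
#' @param repeat_seed integer seed for this split.
#' @return list with `train`, `eval` (commune ids), `seed_commune`,
#'   `d_final` (km).
#' @export
spatial_cv_split <- function(map, config = spatial_cv_config(),
                             repeat_seed = config$seed) {
  com <- map$communes
  n <- nrow(com)
  floor_n <- if (is.null(config$min_train_size)) min_train_default(n)
  else as.integer(config$min_train_size)
  if (floor_n >= n) stop("min_train_size must be smaller than the map")
  with_seed(as.integer(repeat_seed), {
    for (try in 1:50) {
      r <- sample(unique(com$region_id), 1)
      cands <- which(com$region_id == r)
      c0 <- if (length(cands) == 1) cands else sample(cands, 1)
      d2 <- (com$cx - com$cx[c0])^2 + (com$cy - com$cy[c0])^2
      d <- config$d_init
      repeat {
        train <- which(d2 <= d^2)
        if (length(train) >= floor_n) break
        d <- d + config$d_step
      }
      if (length(train) < n) {
        return(list(train = com$commune_id[train],
                    eval = com$commune_id[-train],
                    seed_commune = com$commune_id[c0], d_final = d))
      }
      # radius swallowed the whole map: resample the seed commune
    }
    stop("could not produce a non-degenerate spatial split after 50 tries")
  })
}

#' Standard k-fold assignment
#'
#' Random partition into k folds of near-equal size (sizes differ by at
#' most one); each commune is evaluated exactly once per repeat.
#'
#' @param ids commune ids.
#' @param k number of folds.
#' @param repeat_seed integer seed.
#' @return integer fold label per id (named vector).
#' @export
standard_cv_split <- function(ids, k = 10, repeat_seed = 1L) {
  n <- length(ids)
  if (n < k) stop("fewer communes than folds")
  with_seed(as.integer(repeat_seed),
            stats::setNames(sample(rep(seq_len(k), length.out = n)), ids))
}

#' Prediction metrics: Pearson, Spearman, RMSE
#'
#' Spearman is Pearson on mid-ranks (average ranks on ties). Correlations
#' are NA when either vector has zero variance.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 3.
#' @return named numeric: pearson, spearman, rmse.
#' @export
cv_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  degenerate <- stats::sd(y_true) == 0 || stats::sd(y_pred) == 0
  c(pearson = if (degenerate) NA_real_ else stats::cor(y_true, y_pred),
    spearman = if (degenerate) NA_real_ else
      stats::cor(y_true, y_pred, method = "spearman"),
    rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Repeated cross-validation of the multi-source pipeline
#'
#' Per repeat: draw a split (spatial or standard 10-fold), fit one GP per
#' source on the training communes, predict the evaluation communes, fuse
#' the sources by inverse variance, and score every pipeline (each single
#' source, the fusion, and optionally an OLS baseline on the same splits).
#' Hyperparameters are refitted within every training split. For standard
#' CV the per-repeat metrics pool the predictions of all k folds.
#'
#' @param map a `"commune_map"`.
#' @param sources named list of commune-by-feature matrices (rows aligned
#'   with `map$communes`).
#' @param y target vector aligned with `map$communes`.
#' @param cv a [spatial_cv_config()]; `n_repeats` and `seed` drive both
#'   modes.
#' @param mode `"spatial"` or `"standard"`.
#' @param k folds for standard mode.
#' @param gp_args list of arguments passed on to [gp_fit()].
#' @param baseline optional feature matrix for the linear baseline
#'   (e.g. four columns), fitted by OLS on the same splits.
#' @return object of class `"povgp_cv"`: `repeats` (one row per repeat and
#'   pipeline), `summary` (mean and SD per pipeline), `coverage`
#'   (evaluation counts per commune).
#' @export
run_cv <- function(map, sources, y, cv = spatial_cv_config(),
                   mode = c("spatial", "standard"), k = 10,
                   gp_args = list(), baseline = NULL) {
  mode <- match.arg(mode)
  com <- map$communes
  n <- nrow(com)
  stopifnot(length(y) == n, all(vapply(sources, nrow, integer(1)) == n))
  S <- as.matrix(com[, c("cx", "cy")])
  ids <- com$commune_id
  cover <- stats::setNames(integer(n), ids)
  rows <- list()
  skipped <- 0L
  for (rep_i in seq_len(cv$n_repeats)) {
    rseed <- cv$seed + rep_i
    eval_sets <- if (mode == "spatial") {
      sp <- spatial_cv_split(map, cv, repeat_seed = rseed)
      list(list(train = match(sp$train, ids), eval = match(sp$eval, ids)))
    } else {
      folds <- standard_cv_split(ids, k = k, repeat_seed = rseed)
      lapply(seq_len(k), function(f)
        list(train = which(folds != f), eval = which(folds == f)))
    }
    # pool predictions over the repeat's folds (one fold in spatial mode)
    preds <- list()
    truth <- c()
    eidx_all <- c()
    ok <- TRUE
    for (fs in eval_sets) {
      tr <- fs$train; ev <- fs$eval
      if (stats::sd(y[ev]) == 0) { ok <- FALSE; break }
      fold_pred <- list()
      for (src in names(sources)) {
        X <- sources[[src]]
        fit <- do.call(gp_fit, c(list(X = X[tr, , drop = FALSE],
                                      coords = S[tr, , drop = FALSE],
                                      y = y[tr], source = src,
                                      seed = rseed),
                                 gp_args))
        pr <- predict(fit, X[ev, , drop = FALSE], S[ev, , drop = FALSE])
        pr$commune_id <- ids[ev]
        fold_pred[[src]] <- pr
      }
      if (length(sources) >= 2) {
        fused <- fuse_predictions(fold_pred[[1]], fold_pred[[2]])
        fused <- fused[match(ids[ev], fused$commune_id), ]
        fold_pred[["fused"]] <- data.frame(commune_id = ids[ev],
                                           mean = fused$mean,
                                           variance = fused$variance)
      }
      if (!is.null(baseline)) {
        bX <- cbind(1, baseline[tr, , drop = FALSE])
        bfit <- tryCatch(qr.coef(qr(bX), y[tr]), error = function(e) NULL)
        if (is.null(bfit) || anyNA(bfit)) {
          warning("rank-deficient baseline design; pseudoinverse solve")
          bfit <- drop(MASS_ginv(bX) %*% y[tr])
        }
        bhat <- drop(cbind(1, baseline[ev, , drop = FALSE]) %*% bfit)
        fold_pred[["baseline"]] <- data.frame(commune_id = ids[ev],
                                              mean = bhat, variance = NA)
      }
      for (p in names(fold_pred)) {
        preds[[p]] <- c(preds[[p]], fold_pred[[p]]$mean)
      }
      truth <- c(truth, y[ev])
      eidx_all <- c(eidx_all, ev)
    }
    if (!ok) { skipped <- skipped + 1L; next }
    cover[eidx_all] <- cover[eidx_all] + 1L
    for (p in names(preds)) {
      m <- cv_metrics(truth, preds[[p]])
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = rep_i, pipeline = p,
        pearson = m["pearson"], spearman = m["spearman"], rmse = m["rmse"],
        n_train = length(eval_sets[[1]]$train), n_eval = length(truth),
        stringsAsFactors = FALSE)
    }
  }
  repeats <- do.call(rbind, rows)
  rownames(repeats) <- NULL
  summ <- do.call(rbind, lapply(split(repeats, repeats$pipeline), function(g) {
    data.frame(pipeline = g$pipeline[1], n_repeats = nrow(g),
               pearson = mean(g$pearson, na.rm = TRUE),
               pearson_sd = stats::sd(g$pearson, na.rm = TRUE),
               spearman = mean(g$spearman, na.rm = TRUE),
               spearman_sd = stats::sd(g$spearman, na.rm = TRUE),
               rmse = mean(g$rmse, na.rm = TRUE),
               rmse_sd = stats::sd(g$rmse, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  if (any(cover == 0))
    warning(sum(cover == 0),
            " commune(s) never appeared in an evaluation set")
  structure(list(repeats = repeats, summary = summ,
                 coverage = data.frame(commune_id = ids,
                                       n_evaluated = unname(cover)),
                 skipped = skipped, mode = mode),
            class = "povgp_cv")
}

# minimal Moore-Penrose pseudoinverse (SVD), for rank-deficient baselines
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.povgp_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation, %d repeats (%d skipped)\n",
              x$mode, max(x$repeats$repeat_id), x$skipped))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s r = %.3f (%.3f)  rho = %.3f (%.3f)  RMSE = %.3f (%.3f)\n",
                s$pipeline[i], s$pearson[i], s$pearson_sd[i],
                s$spearman[i], s$spearman_sd[i], s$rmse[i], s$rmse_sd[i]))
  }
  invisible(x)
}

#' Four-feature linear baseline under the same splits
#'
#' Ordinary least squares on a small fixed feature set (the classic
#' call-volume / ownership / nightlights / density quartet, or any
#' synthetic analogue), evaluated under exactly the spatial splits the GP
#' pipelines use.
#'
#' @param features commune-by-feature matrix (typically 4 columns).
#' @param y target vector.
#' @param map a `"commune_map"`.
#' @param cv a [spatial_cv_config()].
#' @param mode `"spatial"` or `"standard"`.
#' @return `"povgp_cv"` object with the single pipeline `"baseline"`.
#' @export
linear_baseline <- function(features, y, map, cv = spatial_cv_config(),
                            mode = "spatial") {
  com <- map$communes
  ids <- com$commune_id
  n <- nrow(com)
  rows <- list()
  for (rep_i in seq_len(cv$n_repeats)) {
    rseed <- cv$seed + rep_i
    splits <- if (mode == "spatial") {
      sp <- spatial_cv_split(map, cv, repeat_seed = rseed)
      list(list(train = match(sp$train, ids), eval = match(sp$eval, ids)))
    } else {
      folds <- standard_cv_split(ids, k = 10, repeat_seed = rseed)
      lapply(1:10, function(f)
        list(train = which(folds != f), eval = which(folds == f)))
    }
    pred <- c(); truth <- c()
    for (fs in splits) {
      bX <- cbind(1, features[fs$train, , drop = FALSE])
      co <- tryCatch(qr.coef(qr(bX), y[fs$train]), error = function(e) NULL)
      if (is.null(co) || anyNA(co)) {
        warning("rank-deficient baseline design; pseudoinverse solve")
        co <- drop(MASS_ginv(bX) %*% y[fs$train])
      }
      pred <- c(pred, drop(cbind(1, features[fs$eval, , drop = FALSE]) %*% co))
      truth <- c(truth, y[fs$eval])
    }
    m <- cv_metrics(truth, pred)
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_id = rep_i, pipeline = "baseline",
      pearson = m["pearson"], spearman = m["spearman"], rmse = m["rmse"],
      n_train = length(splits[[1]]$train), n_eval = length(truth),
      stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, rows)
  rownames(repeats) <- NULL
  summ <- data.frame(pipeline = "baseline", n_repeats = nrow(repeats),
                     pearson = mean(repeats$pearson, na.rm = TRUE),
                     pearson_sd = stats::sd(repeats$pearson, na.rm = TRUE),
                     spearman = mean(repeats$spearman, na.rm = TRUE),
                     spearman_sd = stats::sd(repeats$spearman, na.rm = TRUE),
                     rmse = mean(repeats$rmse, na.rm = TRUE),
                     rmse_sd = stats::sd(repeats$rmse, na.rm = TRUE),
                     stringsAsFactors = FALSE)
  structure(list(repeats = repeats, summary = summ,
                 coverage = NULL, skipped = 0L, mode = mode),
            class = "povgp_cv")
}
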