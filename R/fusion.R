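# Inverse-variance fusion of two source-specific posterior predictions
# into a per-commune Gaussian mixture with exact first and second moments:
#   w_c = (1/s_c^2) / (1/s_c^2 + 1/s_e^2),      w_c + w_e = 1
#   E[y]   = w_c m_c + w_e m_e
#   var[y] = w_c s_c^2 + w_e s_e^2 + w_c w_e (m_c - m_e)^2

#' Inverse-variance mixture weights
#'
#' @param var1,var2 predictive variances of the two sources (vectors
#'   recycle). Variances below `floor` are floored before inverting; if
#'   both fall below the floor the weights are equal (with a warning).
#' @param floor numerical floor on the variances.
#' @return matrix with columns `w1`, `w2`, each row summing to 1.
#' @export
mixture_weights <- function(var1, var2, floor = 1e-12) {
  if (any(var1 < 0, na.rm = TRUE) || any(var2 < 0, na.rm = TRUE))
    stop("negative predictive variance")
  n <- max(length(var1), length(var2))
  v1 <- rep_len(var1, n); v2 <- rep_len(var2, n)
  both <- v1 < floor & v2 < floor
  if (any(both, na.rm = TRUE))
    warning("both variances below floor for ", sum(both),
            " commune(s); using equal weights")
  v1 <- pmax(v1, floor); v2 <- pmax(v2, floor)
  w1 <- (1 / v1) / (1 / v1 + 1 / v2)
  w1[both] <- 0.5
  cbind(w1 = w1, w2 = 1 - w1)
}

#' Fuse two source-specific posterior predictions per commune
#'
#' Combines aligned predictions (same commune on both inputs) into the
#' inverse-variance-weighted mixture. The fused variance carries the
#' between-source disagreement term `w_c w_e (m_c - m_e)^2`, so it can
#' exceed both component variances when the sources disagree. The
#' `best_source` label marks the smaller-variance component (`"tie"` on
#' exact equality). Communes present in only one input pass through
#' unfused with `fused = FALSE`.
#'
#' @param pred1,pred2 data.frames with columns `commune_id`, `mean`,
#'   `variance` (and optionally `source`; defaults `"cdr"`, `"env"`).
#' @return data.frame: commune_id, w1, w2, mean, variance, best_source,
#'   fused.
#' @export
fuse_predictions <- function(pred1, pred2) {
  s1 <- if (!is.null(pred1$source)) pred1$source[1] else "cdr"
  s2 <- if (!is.null(pred2$source)) pred2$source[1] else "env"
  if (is.null(pred1$commune_id)) pred1$commune_id <- rownames(pred1)
  if (is.null(pred2$commune_id)) pred2$commune_id <- rownames(pred2)
  common <- intersect(pred1$commune_id, pred2$commune_id)
  only1 <- setdiff(pred1$commune_id, common)
  only2 <- setdiff(pred2$commune_id, common)
  a <- pred1[match(common, pred1$commune_id), , drop = FALSE]
  b <- pred2[match(common, pred2$commune_id), , drop = FALSE]
  w <- mixture_weights(a$variance, b$variance)
  mu <- w[, 1] * a$mean + w[, 2] * b$mean
  v <- w[, 1] * a$variance + w[, 2] * b$variance +
    w[, 1] * w[, 2] * (a$mean - b$mean)^2
  best <- ifelse(a$variance < b$variance, s1,
                 ifelse(b$variance < a$variance, s2, "tie"))
  out <- data.frame(commune_id = common, w1 = w[, 1], w2 = w[, 2],
                    mean = mu, variance = v, best_source = best,
                    fused = TRUE, stringsAsFactors = FALSE)
  pass <- function(p, ids, w1, src) {
    if (!length(ids)) return(NULL)
    q <- p[match(ids, p$commune_id), , drop = FALSE]
    data.frame(commune_id = ids, w1 = w1, w2 = 1 - w1, mean = q$mean,
               variance = q$variance, best_source = src, fused = FALSE,
               stringsAsFactors = FALSE)
  }
  out <- rbind(out, pass(pred1, only1, 1, s1), pass(pred2, only2, 0, s2))
  rownames(out) <- NULL
  out
}

#' Per-commune best-source table
#'
#' @param fused output of [fuse_predictions()].
#' @return list with `labels` (commune_id, best_source) and `counts`
#'   (table of labels).
#' @export
best_source_map <- function(fused) {
  labels <- fused[, c("commune_id", "best_source")]
  list(labels = labels, counts = table(labels$best_source))
}
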