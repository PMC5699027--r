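# Alkire-Foster multidimensional deprivation statistics from household
# microdata: weighted deprivation scores, commune headcount H, intensity A,
# MPI = H x A, and per-indicator deprivation proportions.

#' The 10-indicator global MPI weighting scheme
#'
#' Three dimensions: education (years of schooling, school attendance) and
#' health (child mortality, nutrition) indicators weigh 1/6 each; the six
#' standard-of-living indicators (cooking fuel, sanitation, water,
#' electricity, floor, assets) weigh 1/18 each. Every dimension sums to
#' 1/3 and the weights sum to 1.
#'
#' @return data.frame with columns `indicator`, `dimension`, `weight`.
#' @export
mpi_scheme <- function() {
  data.frame(
    indicator = c("schooling", "attendance", "mortality", "nutrition",
                  "cooking_fuel", "sanitation", "water", "electricity",
                  "floor", "assets"),
    dimension = c("education", "education", "health", "health",
                  rep("living", 6)),
    weight = c(rep(1 / 6, 4), rep(1 / 18, 6)),
    stringsAsFactors = FALSE)
}

#' Household deprivation vectors and weighted scores
#'
#' Builds the binary deprivation vector per household (optionally from raw
#' achievements via per-indicator cutoff functions: deprived iff
#' achievement <= cutoff), the weighted score `c_i = sum_d w_d dep_{i,d}`
#' and the poverty flag `c_i > theta` (strict; a household at exactly
#' theta is not poor).
#'
#' Missing indicators: a household's score is computed over the observed
#' indicators with weights renormalized, provided at least 2/3 of the
#' total weight is observed; otherwise the household is dropped.
#'
#' @param households data.frame with `household_id`, `commune_id` and the
#'   10 indicator columns of [mpi_scheme()] (binary, or raw achievements
#'   when `cutoffs` is given).
#' @param scheme indicator scheme, see [mpi_scheme()].
#' @param theta poverty cutoff on the weighted score (default 0.3).
#' @param cutoffs optional named list of per-indicator cutoff values or
#'   functions mapping raw achievements to binary deprivation.
#' @return data.frame: household_id, commune_id, the binary indicators,
#'   `c_score`, `is_poor`; attributes `theta`, `scheme`, `n_dropped`.
#' @export
deprivation_scores <- function(households, scheme = mpi_scheme(),
                               theta = 0.3, cutoffs = NULL) {
  stopifnot(all(c("household_id", "commune_id") %in% names(households)),
            theta > 0, theta < 1)
  miss <- setdiff(scheme$indicator, names(households))
  if (length(miss))
    stop("missing indicator columns: ", paste(miss, collapse = ", "))
  dep <- as.matrix(households[, scheme$indicator, drop = FALSE])
  if (!is.null(cutoffs)) {
    for (ind in names(cutoffs)) {
      z <- cutoffs[[ind]]
      dep[, ind] <- if (is.function(z)) as.numeric(z(dep[, ind]))
      else as.numeric(dep[, ind] <= z)
    }
  }
  bad <- dep[!is.na(dep)]
  if (!all(bad %in% c(0, 1)))
    stop("indicators must be binary after cutoffs are applied")
  w <- scheme$weight
  obs <- !is.na(dep)
  wobs <- drop(obs %*% w)
  keep <- wobs >= 2 / 3 - 1e-12
  depk <- dep[keep, , drop = FALSE]
  obsk <- obs[keep, , drop = FALSE]
  wk <- wobs[keep]
  num <- drop(ifelse(obsk, depk, 0) %*% w)
  c_score <- num / wk
  out <- data.frame(household_id = households$household_id[keep],
                    commune_id = households$commune_id[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(depk))
  out$c_score <- c_score
  out$is_poor <- c_score > theta
  attr(out, "theta") <- theta
  attr(out, "scheme") <- scheme
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Commune-level Alkire-Foster statistics
#'
#' Headcount `H_j` = share of households with `c_i > theta`; intensity
#' `A_j` = mean score among the poor (NA when the commune has no poor
#' households); `MPI_j = H_j * A_j` (0 when H = 0). Per-indicator
#' proportions divide deprived households by households with the
#' indicator observed.
#'
#' @param scores output of [deprivation_scores()].
#' @param theta poverty cutoff; defaults to the one stored on `scores`.
#' @return data.frame, one row per commune: commune_id, n_households, H,
#'   A, MPI and one proportion column per indicator (`prop_<indicator>`).
#' @export
commune_stats <- function(scores, theta = attr(scores, "theta")) {
  scheme <- attr(scores, "scheme")
  if (is.null(scheme)) scheme <- mpi_scheme()
  if (is.null(theta)) theta <- 0.3
  poor <- scores$c_score > theta
  out <- lapply(split(seq_len(nrow(scores)), scores$commune_id), function(idx) {
    g <- scores[idx, , drop = FALSE]
    gp <- poor[idx]
    H <- mean(gp)
    A <- if (any(gp)) mean(g$c_score[gp]) else NA_real_
    row <- list(commune_id = g$commune_id[1], n_households = nrow(g),
                H = H, A = A, MPI = if (any(gp)) H * A else 0)
    for (ind in scheme$indicator) {
      v <- g[[ind]]
      row[[paste0("prop_", ind)]] <-
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$commune_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Alkire-Foster statistics over a grid of poverty cutoffs
#'
#' Recomputes [commune_stats()] for each theta in the grid (default 0.2
#' to 0.75). H is non-increasing in theta for every commune.
#'
#' @param scores output of [deprivation_scores()].
#' @param theta_grid cutoffs in (0, 1).
#' @return data.frame stacking the per-theta commune statistics with a
#'   leading `theta` column.
#' @export
theta_sweep <- function(scores, theta_grid = seq(0.2, 0.75, by = 0.05)) {
  stopifnot(all(theta_grid > 0), all(theta_grid < 1))
  out <- lapply(theta_grid, function(th) {
    st <- commune_stats(scores, theta = th)
    cbind(theta = th, st)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
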