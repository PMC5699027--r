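# Seeded synthetic generators: commune maps, antennas, CDR event logs,
# household censuses and two-source feature tables with the statistical
# structure the downstream model assumes. Everything is driven by a single
# configuration object and is bit-reproducible for a fixed seed.

#' Configuration for the synthetic generators
#'
#' Defaults describe the study geography the package targets: 552 communes
#' (121 urban, 431 rural) grouped into 14 regions on a 700 km square, a
#' spatial length-scale of 50 km, and a sparse linear signal over 8
#' features per source.
#'
#' @param n_communes number of communes (Voronoi cells) on the map.
#' @param n_urban number of communes flagged urban (the smallest cells).
#' @param n_regions number of spatially contiguous regions.
#' @param map_extent_km side of the square map, km.
#' @param n_features named or unnamed length-2 vector: features per source
#'   (cdr, env).
#' @param beta_true list with per-source true coefficient vectors.
#' @param kernel list with `sigma_f2`, `ell`, `ell_s` (km), `sigma_n2`
#'   used by the forward GP draw.
#' @param households_per_commune length-2 range of household counts.
#' @param subscribers_per_commune length-2 range of subscriber counts for
#'   rural communes.
#' @param urban_subscriber_factor multiplier on subscriber counts in urban
#'   communes (urban centres are denser in both people and towers).
#' @param events_per_month Poisson mean of monthly events per subscriber.
#' @param nocturnal_fraction probability an event falls in the 19:00-07:00
#'   window.
#' @param home_night_prob probability a nocturnal event is placed at the
#'   subscriber's home antenna.
#' @param day_home_prob probability a daytime event stays at the home
#'   antenna (otherwise a nearby antenna is used).
#' @param extra_urban_antennas additional antennas per urban commune.
#' @param frailty logical; couple a household's indicators through a shared
#'   latent uniform (positive within-household correlation).
#' @param seed integer master seed.
#' @return classed list `"povgp_config"`.
#' @export
synthetic_config <- function(n_communes = 552, n_urban = 121, n_regions = 14,
                             map_extent_km = 700,
                             n_features = c(cdr = 8, env = 8),
                             beta_true = NULL,
                             kernel = list(sigma_f2 = 0.5, ell = 3,
                                           ell_s = 50, sigma_n2 = 0.1),
                             households_per_commune = c(150, 400),
                             subscribers_per_commune = c(20, 60),
                             urban_subscriber_factor = 3,
                             events_per_month = 25,
                             nocturnal_fraction = 0.35,
                             home_night_prob = 0.9,
                             day_home_prob = 0.5,
                             extra_urban_antennas = 2,
                             frailty = FALSE,
                             seed = 1L) {
  if (n_urban > n_communes) stop("n_urban must not exceed n_communes")
  if (n_regions > n_communes) stop("n_regions must not exceed n_communes")
  stopifnot(map_extent_km > 0, length(n_features) == 2,
            kernel$sigma_f2 >= 0, kernel$sigma_n2 >= 0,
            kernel$ell > 0, kernel$ell_s > 0,
            nocturnal_fraction >= 0, nocturnal_fraction <= 1,
            home_night_prob >= 0, home_night_prob <= 1,
            day_home_prob >= 0, day_home_prob <= 1,
            length(households_per_commune) == 2,
            length(subscribers_per_commune) == 2,
            events_per_month >= 0)
  if (is.null(names(n_features))) names(n_features) <- c("cdr", "env")
  if (is.null(beta_true)) {
    beta_true <- lapply(n_features, function(d) {
      b <- numeric(d)
      k <- min(3, d)
      b[seq_len(k)] <- c(1, -0.8, 0.6)[seq_len(k)]
      b
    })
  }
  structure(list(
    n_communes = as.integer(n_communes), n_urban = as.integer(n_urban),
    n_regions = as.integer(n_regions), map_extent_km = map_extent_km,
    n_features = n_features, beta_true = beta_true, kernel = kernel,
    households_per_commune = as.integer(households_per_commune),
    subscribers_per_commune = as.integer(subscribers_per_commune),
    urban_subscriber_factor = urban_subscriber_factor,
    events_per_month = events_per_month,
    nocturnal_fraction = nocturnal_fraction,
    home_night_prob = home_night_prob, day_home_prob = day_home_prob,
    extra_urban_antennas = as.integer(extra_urban_antennas),
    frailty = frailty, seed = as.integer(seed)
  ), class = "povgp_config")
}

#' Generate a synthetic commune map
#'
#' Voronoi tessellation of uniformly placed seed points clipped to the
#' square extent. The `n_urban` smallest cells are flagged urban (a proxy
#' for density); regions are formed by k-means clustering of the seed
#' points into `n_regions` spatially contiguous groups.
#'
#' @param config a [synthetic_config()].
#' @return object of class `"commune_map"`: list with `communes`
#'   (data.frame: commune_id, region_id, is_urban, cx, cy, area_km2),
#'   `polygons` (named list of vertex matrices) and `extent`
#'   (xmin, xmax, ymin, ymax).
#' @export
generate_commune_map <- function(config) {
  stopifnot(inherits(config, "povgp_config"))
  n <- config$n_communes
  L <- config$map_extent_km
  extent <- c(0, L, 0, L)
  with_seed(config$seed, {
    pts <- cbind(stats::runif(n, 0, L), stats::runif(n, 0, L))
    cells <- voronoi_cells(pts, extent)
    areas <- vapply(cells, poly_area, numeric(1))
    cents <- t(vapply(cells, poly_centroid, numeric(2)))
    urban <- rep(FALSE, n)
    urban[order(areas)[seq_len(config$n_urban)]] <- TRUE
    region <- if (config$n_regions >= n) {
      seq_len(n)
    } else if (config$n_regions == 1L) {
      rep(1L, n)
    } else {
      stats::kmeans(pts, centers = config$n_regions, nstart = 5,
                    iter.max = 50)$cluster
    }
    ids <- sprintf("C%03d", seq_len(n))
    names(cells) <- ids
    structure(list(
      communes = data.frame(commune_id = ids,
                            region_id = sprintf("R%02d", region),
                            is_urban = urban,
                            cx = cents[, 1], cy = cents[, 2],
                            area_km2 = areas,
                            stringsAsFactors = FALSE),
      polygons = cells, seed_points = pts, extent = extent,
      config = config
    ), class = "commune_map")
  })
}

#' @export
print.commune_map <- function(x, ...) {
  cat(sprintf("commune map: %d communes (%d urban, %d rural), %d regions, %g km extent\n",
              nrow(x$communes), sum(x$communes$is_urban),
              sum(!x$communes$is_urban),
              length(unique(x$communes$region_id)),
              x$extent[2] - x$extent[1]))
  invisible(x)
}

#' Place antennas on a commune map
#'
#' One antenna at every commune centre (the commune's Voronoi generator
#' point, so each rural antenna serves exactly its commune) plus
#' `extra_urban_antennas` additional antennas at random interior points of
#' each urban commune (urban centres are denser in towers).
#'
#' @param map a `"commune_map"`.
#' @param config the generating [synthetic_config()].
#' @return data.frame with antenna_id, commune_id, x, y.
#' @export
place_antennas <- function(map, config = map$config) {
  com <- map$communes
  with_seed(config$seed + 1L, {
    xs <- map$seed_points[, 1]; ys <- map$seed_points[, 2]
    owner <- com$commune_id
    for (i in which(com$is_urban)) {
      poly <- map$polygons[[com$commune_id[i]]]
      bb <- c(range(poly[, 1]), range(poly[, 2]))
      k <- 0
      while (k < config$extra_urban_antennas) {
        px <- stats::runif(1, bb[1], bb[2])
        py <- stats::runif(1, bb[3], bb[4])
        if (point_in_poly(c(px, py), poly)) {
          xs <- c(xs, px); ys <- c(ys, py); owner <- c(owner, com$commune_id[i])
          k <- k + 1
        }
      }
    }
    data.frame(antenna_id = sprintf("A%04d", seq_along(xs)),
               commune_id = owner, x = xs, y = ys,
               stringsAsFactors = FALSE)
  })
}

# even-odd ray casting; boundary points count as inside
point_in_poly <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xcross <- xi + (pt[2] - yi) / (yj - yi) * (xj - xi)
      if (pt[1] < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Draw a single-source latent field from the forward model
#'
#' Draws standard-normal features X, a GP realization f with the product
#' feature-by-spatial kernel evaluated at (X, centroids), and independent
#' noise, and returns `y = X beta_true + f + eps` together with each
#' component so tests can verify the decomposition exactly.
#'
#' @param map a `"commune_map"`.
#' @param config a [synthetic_config()]; `config$kernel` and
#'   `config$beta_true[[source]]` define the draw.
#' @param source `"cdr"` or `"env"` (selects beta_true and the seed
#'   stream).
#' @return list with `y`, `X`, `S`, `f`, `eps`, `beta_true`, `params`.
#' @export
generate_latent_field <- function(map, config = map$config, source = "cdr") {
  stopifnot(nrow(map$communes) > 0)
  n <- nrow(map$communes)
  d <- config$n_features[[source]]
  beta <- config$beta_true[[source]]
  stopifnot(length(beta) == d)
  S <- as.matrix(map$communes[, c("cx", "cy")])
  off <- if (source == "cdr") 2L else 3L
  with_seed(config$seed + off, {
    X <- matrix(stats::rnorm(n * d), n, d,
                dimnames = list(map$communes$commune_id,
                                paste0(source, "_f", seq_len(d))))
    if (config$kernel$sigma_f2 == 0) {
      f <- numeric(n)
    } else {
      K <- gp_kernel(X, S, X, S, config$kernel)
      U <- tryCatch(chol_jitter(K), error = function(e)
        stop("simulated covariance not positive definite after jitter"))
      f <- drop(crossprod(U, stats::rnorm(n)))
    }
    eps <- if (config$kernel$sigma_n2 == 0) numeric(n) else
      stats::rnorm(n, 0, sqrt(config$kernel$sigma_n2))
    y <- drop(X %*% beta) + f + eps
    list(y = y, X = X, S = S, f = f, eps = eps, beta_true = beta,
         params = config$kernel)
  })
}

#' Generate a shared latent deprivation surface and two linked sources
#'
#' Draws one spatially autocorrelated latent deprivation field u (a
#' zero-mean GP on the commune centroids with length-scale
#' `config$kernel$ell_s`), sets the target `y = u + noise`, and builds two
#' feature tables whose first `n_informative` columns load linearly on u
#' with independent noise while the remaining columns are pure noise. Both
#' sources therefore carry signal about the same field, which is the
#' premise of the inverse-variance fusion.
#'
#' @param map a `"commune_map"`.
#' @param config a [synthetic_config()].
#' @param n_informative informative columns per source.
#' @param loadings correlation of each informative column with u.
#' @return list with `y`, `u`, `features` (named list of matrices, one per
#'   source), `S`.
#' @export
generate_multisource <- function(map, config = map$config,
                                 n_informative = 3,
                                 loadings = c(0.8, 0.7, 0.6)) {
  n <- nrow(map$communes)
  S <- as.matrix(map$communes[, c("cx", "cy")])
  stopifnot(n_informative <= min(config$n_features),
            length(loadings) >= n_informative)
  with_seed(config$seed + 4L, {
    D2s <- sq_dist(S)
    Ku <- exp(-D2s / (2 * config$kernel$ell_s^2))
    U <- chol_jitter(Ku)
    u <- drop(crossprod(U, stats::rnorm(n)))
    y <- u + stats::rnorm(n, 0, sqrt(max(config$kernel$sigma_n2, 1e-12)))
    uz <- (u - mean(u)) / stats::sd(u)
    feats <- lapply(names(config$n_features), function(src) {
      d <- config$n_features[[src]]
      X <- matrix(stats::rnorm(n * d), n, d)
      for (j in seq_len(n_informative)) {
        a <- loadings[j]
        X[, j] <- a * uz + sqrt(1 - a^2) * stats::rnorm(n)
      }
      colnames(X) <- paste0(src, "_f", seq_len(d))
      rownames(X) <- map$communes$commune_id
      X
    })
    names(feats) <- names(config$n_features)
    list(y = y, u = u, features = feats, S = S)
  })
}

#' Per-commune indicator probabilities implied by a latent field
#'
#' Maps a latent deprivation field to per-indicator deprivation
#' probabilities through a logistic link: more deprived communes (higher
#' u) are deprived with higher probability in every indicator.
#'
#' @param u latent field, one value per commune.
#' @param base_logits length-10 baseline log-odds per indicator (defaults
#'   give deprivation rates between roughly 0.2 and 0.7).
#' @param slope common slope on the standardized field.
#' @return matrix n_communes x 10, entries in (0, 1).
#' @export
indicator_probs_from_latent <- function(u,
                                        base_logits = c(0.2, 0.1, -1.0, -0.6,
                                                        0.8, 0.3, -0.2, 0.5,
                                                        -0.4, 0.0),
                                        slope = 1.2) {
  stopifnot(length(base_logits) == 10)
  uz <- (u - mean(u)) / stats::sd(u)
  p <- vapply(base_logits, function(b) stats::plogis(b + slope * uz),
              numeric(length(u)))
  colnames(p) <- mpi_scheme()$indicator
  p
}

#' Generate a household deprivation census
#'
#' Households are drawn per commune (count uniform in
#' `config$households_per_commune`); indicator d of household i is deprived
#' with the commune's probability. With `config$frailty` a shared uniform
#' per household drives all indicators (comonotone thresholding), inducing
#' positive within-household correlation.
#'
#' @param map a `"commune_map"`.
#' @param probs matrix n_communes x 10 of per-indicator deprivation
#'   probabilities (rows follow `map$communes`).
#' @param config a [synthetic_config()].
#' @return data.frame: household_id, commune_id and 10 binary indicator
#'   columns named after [mpi_scheme()].
#' @export
generate_household_table <- function(map, probs, config = map$config) {
  stopifnot(nrow(probs) == nrow(map$communes), ncol(probs) == 10)
  if (any(probs < 0 | probs > 1)) stop("indicator probabilities must lie in [0, 1]")
  rng <- config$households_per_commune
  inds <- mpi_scheme()$indicator
  with_seed(config$seed + 5L, {
    nh <- if (rng[1] == rng[2]) rep(rng[1], nrow(map$communes)) else
      sample(rng[1]:rng[2], nrow(map$communes), replace = TRUE)
    total <- sum(nh)
    commune <- rep(map$communes$commune_id, nh)
    P <- probs[rep(seq_len(nrow(probs)), nh), , drop = FALSE]
    if (config$frailty) {
      # shared latent uniform: indicator deprived iff frailty < p
      fr <- stats::runif(total)
      dep <- (fr < P) * 1L
    } else {
      dep <- (matrix(stats::runif(total * 10), total, 10) < P) * 1L
    }
    colnames(dep) <- inds
    out <- data.frame(household_id = sprintf("H%06d", seq_len(total)),
                      commune_id = commune, stringsAsFactors = FALSE)
    cbind(out, as.data.frame(dep))
  })
}

#' Generate a synthetic CDR event log
#'
#' Every subscriber gets a ground-truth home antenna in their commune, a
#' personal contact pool with Zipf-like interaction weights, and Poisson
#' monthly event counts. Nocturnal events (19:00-07:00) are placed at the
#' home antenna with probability `home_night_prob`; other events are at
#' the home antenna with probability `day_home_prob` or at one of the
#' three nearest antennas. The simulated year is 2013 (UTC).
#'
#' @param map a `"commune_map"`.
#' @param antennas data.frame from [place_antennas()].
#' @param config a [synthetic_config()].
#' @return list with `events` (data.frame: subscriber_id, antenna_id,
#'   timestamp, kind, duration_s, direction, peer_id) and `truth`
#'   (data.frame: subscriber_id, home_antenna, home_commune).
#' @export
generate_cdr_log <- function(map, antennas, config = map$config) {
  if (nrow(antennas) == 0) stop("no antennas placed")
  com <- map$communes
  rng <- config$subscribers_per_commune
  # 3 nearest other antennas, for daytime mobility
  D <- sq_dist(as.matrix(antennas[, c("x", "y")]))
  nearby <- lapply(seq_len(nrow(antennas)), function(i) {
    ord <- order(D[i, ])
    ord <- ord[ord != i]
    utils::head(ord, 3)
  })
  month_starts <- as.POSIXct(sprintf("2013-%02d-01", 1:12), tz = "UTC")
  month_len <- as.numeric(difftime(c(month_starts[-1],
                                     as.POSIXct("2014-01-01", tz = "UTC")),
                                   month_starts, units = "secs"))
  with_seed(config$seed + 6L, {
    nsub <- if (rng[1] == rng[2]) rep(rng[1], nrow(com)) else
      sample(rng[1]:rng[2], nrow(com), replace = TRUE)
    fac <- if (is.null(config$urban_subscriber_factor)) 1 else
      config$urban_subscriber_factor
    nsub <- as.integer(round(nsub * ifelse(com$is_urban, fac, 1)))
    total <- sum(nsub)
    sub_commune <- rep(com$commune_id, nsub)
    sub_id <- sprintf("S%05d", seq_len(total))
    # home antenna: uniform among the commune's antennas
    ant_by_commune <- split(seq_len(nrow(antennas)), antennas$commune_id)
    home_idx <- vapply(sub_commune, function(cid) {
      cand <- ant_by_commune[[cid]]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, integer(1))
    truth <- data.frame(subscriber_id = sub_id,
                        home_antenna = antennas$antenna_id[home_idx],
                        home_commune = sub_commune,
                        stringsAsFactors = FALSE)
    rows <- vector("list", total)
    for (i in seq_len(total)) {
      npeer <- sample(5:15, 1)
      peers <- sprintf("P%05d_%02d", i, seq_len(npeer))
      pw <- 1 / seq_len(npeer)  # Zipf-like contact weights
      nm <- stats::rpois(12, config$events_per_month)
      ne <- sum(nm)
      if (ne == 0) next
      mon <- rep(1:12, nm)
      noct <- stats::runif(ne) < config$nocturnal_fraction
      hour <- ifelse(noct,
                     (19 + stats::runif(ne) * 12) %% 24,  # [19,24) U [0,7)
                     7 + stats::runif(ne) * 12)           # [7,19)
      frac <- stats::runif(ne)  # position of the day within the month
      day_sec <- floor(frac * (month_len[mon] / 86400)) * 86400
      ts <- month_starts[mon] + day_sec + floor(hour * 3600) +
        sample(0:59, ne, replace = TRUE)
      at_home <- ifelse(noct,
                        stats::runif(ne) < config$home_night_prob,
                        stats::runif(ne) < config$day_home_prob)
      ant <- integer(ne)
      ant[at_home] <- home_idx[i]
      if (any(!at_home)) {
        nb <- nearby[[home_idx[i]]]
        ant[!at_home] <- nb[sample.int(length(nb), sum(!at_home),
                                       replace = TRUE)]
      }
      kind <- ifelse(stats::runif(ne) < 0.6, "call", "text")
      rows[[i]] <- data.frame(
        subscriber_id = sub_id[i],
        antenna_id = antennas$antenna_id[ant],
        timestamp = ts,
        kind = kind,
        duration_s = ifelse(kind == "call",
                            pmax(1, round(stats::rexp(ne, 1 / 120))), NA_real_),
        direction = ifelse(stats::runif(ne) < 0.5, "out", "in"),
        peer_id = peers[sample.int(npeer, ne, replace = TRUE, prob = pw)],
        stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(events) <- NULL
    list(events = events, truth = truth)
  })
}

#' Write a synthetic bundle to disk
#'
#' Map and antennas as GeoJSON, event log and households as CSV, the
#' configuration as JSON — the plain-text exchange formats of the package.
#'
#' @param dir output directory (created if missing).
#' @param map,antennas,log,households,config artifacts from the generators
#'   (any may be NULL to skip).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(dir, map = NULL, antennas = NULL,
                                   log = NULL, households = NULL,
                                   config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(map))
    write_geojson_polygons(map$polygons,
                           map$communes[, c("commune_id", "region_id", "is_urban")],
                           file.path(dir, "communes.geojson"))
  if (!is.null(antennas))
    write_geojson_points(as.matrix(antennas[, c("x", "y")]),
                         antennas[, c("antenna_id", "commune_id")],
                         file.path(dir, "antennas.geojson"))
  if (!is.null(log)) {
    ev <- log$events
    ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(ev, file.path(dir, "cdr_events.csv"), row.names = FALSE)
    utils::write.csv(log$truth, file.path(dir, "cdr_truth.csv"),
                     row.names = FALSE)
  }
  if (!is.null(households))
    utils::write.csv(households, file.path(dir, "households.csv"),
                     row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
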