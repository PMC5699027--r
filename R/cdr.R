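# CDR aggregation: home-antenna assignment, subscriber retention filters,
# monthly subscriber features, antenna means and Voronoi-overlap-weighted
# commune means.
#
# Conventions (documented so tests are unambiguous):
#  - the nocturnal window is [19:00, 07:00), half-open — 07:00 is daytime;
#  - modal-antenna ties break to the lexicographically smallest antenna_id;
#  - entropies are in natural log (nats);
#  - a month "qualifies" for retention when it has >= 5 interactions AND a
#    defined monthly home; retention requires >= 6 qualifying months.

event_month <- function(timestamp) as.integer(format(timestamp, "%m"))
event_hour <- function(timestamp) as.integer(format(timestamp, "%H"))

#' Assign monthly and yearly home antennas
#'
#' The monthly home is the antenna with the most events in the nocturnal
#' window (19:00-07:00) that month; ties break to the smallest antenna_id.
#' The yearly home is the modal monthly home (same tie rule). Subscribers
#' with no nocturnal events in any month have no home and are flagged
#' not retained.
#'
#' @param events CDR event data.frame (subscriber_id, antenna_id,
#'   timestamp, ...); timestamps must span at most one year.
#' @return list with `monthly` (subscriber_id, month, home_antenna) and
#'   `yearly` (subscriber_id, home_antenna, n_months, retained).
#' @export
assign_home_antennas <- function(events) {
  mon <- event_month(events$timestamp)
  hr <- event_hour(events$timestamp)
  noct <- is_nocturnal_hour(hr)
  subs <- sort(unique(events$subscriber_id))
  ne <- events[noct, , drop = FALSE]
  nmon <- mon[noct]
  if (nrow(ne)) {
    key <- paste(ne$subscriber_id, nmon, sep = "\r")
    tab <- table(key, ne$antenna_id)
    # per subscriber-month: antenna with max count, ties -> smallest id
    ants <- colnames(tab)[order(colnames(tab))]
    tab <- tab[, order(colnames(tab)), drop = FALSE]
    pick <- apply(tab, 1, function(row) ants[which.max(row)])
    parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
    monthly <- data.frame(
      subscriber_id = vapply(parts, `[`, character(1), 1),
      month = as.integer(vapply(parts, `[`, character(1), 2)),
      home_antenna = unname(pick),
      stringsAsFactors = FALSE)
    monthly <- monthly[order(monthly$subscriber_id, monthly$month), ]
    rownames(monthly) <- NULL
  } else {
    monthly <- data.frame(subscriber_id = character(0), month = integer(0),
                          home_antenna = character(0),
                          stringsAsFactors = FALSE)
  }
  yearly <- do.call(rbind, lapply(subs, function(s) {
    mh <- monthly$home_antenna[monthly$subscriber_id == s]
    if (!length(mh))
      return(data.frame(subscriber_id = s, home_antenna = NA_character_,
                        n_months = 0L, retained = FALSE,
                        stringsAsFactors = FALSE))
    tt <- table(mh)
    win <- sort(names(tt)[tt == max(tt)])[1]  # modal, ties -> smallest id
    data.frame(subscriber_id = s, home_antenna = win,
               n_months = length(mh), retained = TRUE,
               stringsAsFactors = FALSE)
  }))
  rownames(yearly) <- NULL
  list(monthly = monthly, yearly = yearly)
}

#' Retention filter for subscribers
#'
#' A month qualifies when the subscriber has at least `min_events`
#' interactions and a defined monthly home antenna; the subscriber is
#' retained when at least `min_months` months qualify (half of the year by
#' default).
#'
#' @param events CDR event data.frame.
#' @param assignments result of [assign_home_antennas()].
#' @param min_events minimum interactions per qualifying month.
#' @param min_months minimum qualifying months for retention.
#' @return character vector of retained subscriber ids (possibly empty).
#' @export
filter_subscribers <- function(events, assignments, min_events = 5,
                               min_months = 6) {
  if (!nrow(events)) return(character(0))
  mon <- event_month(events$timestamp)
  cnt <- table(events$subscriber_id, mon)
  homes <- assignments$monthly
  retained <- character(0)
  for (s in rownames(cnt)) {
    months_with_home <- homes$month[homes$subscriber_id == s]
    qual <- 0L
    for (m in months_with_home) {
      mc <- if (as.character(m) %in% colnames(cnt)) cnt[s, as.character(m)] else 0
      if (mc >= min_events) qual <- qual + 1L
    }
    if (qual >= min_months) retained <- c(retained, s)
  }
  retained
}

#' Monthly subscriber features from the event log
#'
#' Computes the 13-feature representative set per subscriber-month:
#' active_days, n_interactions_call, n_interactions_text, ratio_call_text,
#' interevent_time_mean, interevent_time_sd (seconds, NA for months with a
#' single event), n_contacts, entropy_of_contacts (nats), percent_nocturnal,
#' percent_initiated, n_antennas, entropy_of_antennas (nats),
#' radius_of_gyration (km, needs antenna coordinates).
#'
#' @param events CDR event data.frame.
#' @param antennas data.frame with antenna_id, x, y (km) for the radius of
#'   gyration.
#' @param subscribers optional subset of subscriber ids.
#' @param months optional subset of months (1-12).
#' @return data.frame, one row per subscriber-month present in the log.
#' @export
compute_subscriber_features <- function(events, antennas,
                                        subscribers = NULL, months = 1:12) {
  if (!is.null(subscribers))
    events <- events[events$subscriber_id %in% subscribers, , drop = FALSE]
  mon <- event_month(events$timestamp)
  keep <- mon %in% months
  events <- events[keep, , drop = FALSE]
  mon <- mon[keep]
  if (!nrow(events)) return(empty_features_df())
  ax <- stats::setNames(antennas$x, antennas$antenna_id)
  ay <- stats::setNames(antennas$y, antennas$antenna_id)
  pieces <- split(seq_len(nrow(events)), list(events$subscriber_id, mon),
                  drop = TRUE)
  out <- lapply(names(pieces), function(nm) {
    idx <- pieces[[nm]]
    ev <- events[idx, , drop = FALSE]
    ev <- ev[order(ev$timestamp), , drop = FALSE]
    ncall <- sum(ev$kind == "call")
    ntext <- sum(ev$kind == "text")
    gaps <- if (nrow(ev) > 1)
      diff(as.numeric(ev$timestamp)) else numeric(0)
    pc <- table(ev$peer_id)
    pa <- table(ev$antenna_id)
    coords <- cbind(ax[names(pa)], ay[names(pa)])
    w <- as.numeric(pa)
    cen <- colSums(coords * w) / sum(w)
    rg <- sqrt(sum(w * ((coords[, 1] - cen[1])^2 +
                          (coords[, 2] - cen[2])^2)) / sum(w))
    data.frame(
      subscriber_id = ev$subscriber_id[1],
      month = event_month(ev$timestamp[1]),
      active_days = length(unique(format(ev$timestamp, "%Y-%m-%d"))),
      n_interactions_call = ncall,
      n_interactions_text = ntext,
      ratio_call_text = if (ntext > 0) ncall / ntext else NA_real_,
      interevent_time_mean = if (length(gaps)) mean(gaps) else NA_real_,
      interevent_time_sd = if (length(gaps) > 1) stats::sd(gaps) else NA_real_,
      n_contacts = length(pc),
      entropy_of_contacts = count_entropy(as.numeric(pc)),
      percent_nocturnal = mean(is_nocturnal_hour(event_hour(ev$timestamp))),
      percent_initiated = mean(ev$direction == "out"),
      n_antennas = length(pa),
      entropy_of_antennas = count_entropy(as.numeric(pa)),
      radius_of_gyration = rg,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$subscriber_id, res$month), ]
  rownames(res) <- NULL
  res
}

empty_features_df <- function() {
  data.frame(subscriber_id = character(0), month = integer(0),
             active_days = integer(0), n_interactions_call = integer(0),
             n_interactions_text = integer(0), ratio_call_text = numeric(0),
             interevent_time_mean = numeric(0),
             interevent_time_sd = numeric(0), n_contacts = integer(0),
             entropy_of_contacts = numeric(0), percent_nocturnal = numeric(0),
             percent_initiated = numeric(0), n_antennas = integer(0),
             entropy_of_antennas = numeric(0), radius_of_gyration = numeric(0),
             stringsAsFactors = FALSE)
}

#' Average subscriber features per home antenna
#'
#' For every antenna a and feature-month column f:
#' `m_a(f) = mean over retained subscribers with yearly home a of m_i(f)`,
#' with missing monthly values excluded from the mean (not imputed).
#' Antennas with no retained subscribers carry no row.
#'
#' @param features output of [compute_subscriber_features()].
#' @param assignments output of [assign_home_antennas()].
#' @param retained subscriber ids kept by [filter_subscribers()].
#' @return data.frame: antenna_id, n_subscribers, then one column per
#'   `<feature>__m<month>`.
#' @export
antenna_feature_means <- function(features, assignments, retained) {
  yr <- assignments$yearly
  yr <- yr[yr$subscriber_id %in% retained & yr$retained, , drop = FALSE]
  feats <- features[features$subscriber_id %in% yr$subscriber_id, ,
                    drop = FALSE]
  if (!nrow(feats) || !nrow(yr)) {
    return(data.frame(antenna_id = character(0), n_subscribers = integer(0),
                      stringsAsFactors = FALSE))
  }
  fcols <- setdiff(names(feats), c("subscriber_id", "month"))
  # wide per subscriber: feature__m<month>
  home <- stats::setNames(yr$home_antenna, yr$subscriber_id)
  feats$antenna_id <- home[feats$subscriber_id]
  out <- lapply(split(feats, feats$antenna_id), function(g) {
    row <- list(antenna_id = g$antenna_id[1],
                n_subscribers = length(unique(g$subscriber_id)))
    for (m in sort(unique(g$month))) {
      gm <- g[g$month == m, , drop = FALSE]
      for (f in fcols) {
        v <- gm[[f]]
        row[[paste0(f, "__m", m)]] <-
          if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  all_cols <- Reduce(union, lapply(out, names))
  out <- lapply(out, function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA_real_
    df[all_cols]
  })
  res <- do.call(rbind, out)
  res <- res[order(res$antenna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Voronoi overlap weights between communes and antenna cells
#'
#' Builds the Voronoi tessellation of the antennas over the map extent and
#' computes `w_{c,a} = Area(c intersect a) / Area(a)` for every
#' commune-antenna pair with positive intersection area.
#'
#' @param map a `"commune_map"`.
#' @param antennas data.frame with antenna_id, x, y.
#' @return data.frame (commune_id, antenna_id, weight); degenerate
#'   zero-area antenna cells are dropped with a warning.
#' @export
voronoi_overlap_weights <- function(map, antennas) {
  cells <- voronoi_cells(as.matrix(antennas[, c("x", "y")]), map$extent)
  areas <- vapply(cells, poly_area, numeric(1))
  degen <- areas <= 1e-12
  if (any(degen))
    warning(sum(degen), " degenerate antenna cell(s) excluded")
  rows <- list()
  for (a in which(!degen)) {
    cell <- cells[[a]]
    bb <- c(range(cell[, 1]), range(cell[, 2]))
    for (ci in seq_along(map$polygons)) {
      poly <- map$polygons[[ci]]
      # cheap bounding-box rejection before the exact clip
      if (max(poly[, 1]) < bb[1] || min(poly[, 1]) > bb[2] ||
          max(poly[, 2]) < bb[3] || min(poly[, 2]) > bb[4]) next
      inter <- clip_polygon_convex(poly, cell)
      ia <- if (is.null(inter)) 0 else poly_area(inter)
      if (ia > 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          commune_id = names(map$polygons)[ci],
          antenna_id = antennas$antenna_id[a],
          weight = ia / areas[a], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Commune feature vector from antenna means and overlap weights
#'
#' `m_c(f) = sum_a w_{c,a} m_a(f) / sum_a w_{c,a}`, with the weight sum
#' renormalized over the antennas that actually carry data for the
#' feature. Communes with no intersecting antenna carrying data get NA and
#' are listed in the `coverage` attribute.
#'
#' @param weights data.frame from [voronoi_overlap_weights()].
#' @param antenna_means data.frame from [antenna_feature_means()].
#' @return data.frame with commune_id and one column per feature-month;
#'   attribute `coverage` reports communes with missing features.
#' @export
commune_feature_vector <- function(weights, antenna_means) {
  fcols <- setdiff(names(antenna_means), c("antenna_id", "n_subscribers"))
  communes <- sort(unique(weights$commune_id))
  am <- antenna_means[match(weights$antenna_id, antenna_means$antenna_id), ,
                      drop = FALSE]
  out <- lapply(communes, function(cid) {
    sel <- weights$commune_id == cid
    w <- weights$weight[sel]
    vals <- am[sel, fcols, drop = FALSE]
    row <- list(commune_id = cid)
    for (f in fcols) {
      v <- vals[[f]]
      ok <- !is.na(v)
      row[[f]] <- if (any(ok)) sum(w[ok] * v[ok]) / sum(w[ok]) else NA_real_
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  nacount <- rowSums(is.na(res[, -1, drop = FALSE]))
  attr(res, "coverage") <- data.frame(commune_id = res$commune_id,
                                      n_missing = nacount,
                                      stringsAsFactors = FALSE)
  res
}

#' Estimate commune populations from antenna subscriber counts
#'
#' Redistributes each antenna's retained-subscriber count over communes by
#' the overlap weights: `N_c = sum_a w_{c,a} N_a`. Used as a sanity check
#' of the Voronoi assignment against known commune populations.
#'
#' @param weights data.frame from [voronoi_overlap_weights()].
#' @param antenna_counts data.frame with antenna_id and n_subscribers.
#' @return data.frame (commune_id, population_estimate).
#' @export
estimate_commune_population <- function(weights, antenna_counts) {
  n <- stats::setNames(antenna_counts$n_subscribers,
                       antenna_counts$antenna_id)
  w <- weights
  w$count <- n[w$antenna_id]
  w$count[is.na(w$count)] <- 0
  agg <- stats::aggregate(list(population_estimate = w$weight * w$count),
                          by = list(commune_id = w$commune_id), FUN = sum)
  agg[order(agg$commune_id), ]
}

#' End-to-end CDR aggregation to a commune feature table
#'
#' Chains home assignment, retention filtering, monthly features, antenna
#' means and the Voronoi-overlap commune means.
#'
#' @param log list from [generate_cdr_log()] (or any list with an
#'   `events` data.frame).
#' @param map a `"commune_map"`.
#' @param antennas antenna data.frame.
#' @param months months to compute features for.
#' @return list with `commune_features`, `antenna_means`, `weights`,
#'   `assignments`, `retained`.
#' @export
aggregate_cdr <- function(log, map, antennas, months = 1:12) {
  ev <- if (is.data.frame(log)) log else log$events
  asg <- assign_home_antennas(ev)
  kept <- filter_subscribers(ev, asg)
  feats <- compute_subscriber_features(ev, antennas, subscribers = kept,
                                       months = months)
  am <- antenna_feature_means(feats, asg, kept)
  w <- voronoi_overlap_weights(map, antennas)
  cf <- commune_feature_vector(w, am)
  list(commune_features = cf, antenna_means = am, weights = w,
       assignments = asg, retained = kept)
}
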