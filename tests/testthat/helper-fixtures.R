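# shared fixtures: tiny seeded configurations and hand-built event logs

small_config <- function(seed = 7L, ...) {
  synthetic_config(n_communes = 25, n_urban = 5, n_regions = 4,
                   map_extent_km = 200,
                   households_per_commune = c(40, 60),
                   subscribers_per_commune = c(3, 6),
                   events_per_month = 20, seed = seed, ...)
}

small_map <- function(seed = 7L, ...) generate_commune_map(small_config(seed, ...))

# build an event data.frame from short specs; hour decides nocturnality
make_events <- function(subscriber, antenna, month, hour,
                        kind = "call", direction = "out",
                        peer = "P1", day = 5, minute = 0) {
  n <- max(length(subscriber), length(antenna), length(month), length(hour))
  ts <- as.POSIXct(sprintf("2013-%02d-%02d %02d:%02d:00",
                           rep_len(month, n), rep_len(day, n),
                           rep_len(hour, n), rep_len(minute, n)),
                   tz = "UTC")
  data.frame(subscriber_id = rep_len(subscriber, n),
             antenna_id = rep_len(antenna, n),
             timestamp = ts,
             kind = rep_len(kind, n),
             duration_s = ifelse(rep_len(kind, n) == "call", 60, NA_real_),
             direction = rep_len(direction, n),
             peer_id = rep_len(peer, n),
             stringsAsFactors = FALSE)
}

# brute-force Alkire-Foster oracle: explicit loops, no vectorization
af_oracle <- function(households, theta = 0.3) {
  sch <- mpi_scheme()
  out <- list()
  for (cid in sort(unique(households$commune_id))) {
    hh <- households[households$commune_id == cid, , drop = FALSE]
    cs <- numeric(nrow(hh))
    for (i in seq_len(nrow(hh))) {
      ci <- 0
      for (d in seq_len(10)) {
        ci <- ci + sch$weight[d] * hh[[sch$indicator[d]]][i]
      }
      cs[i] <- ci
    }
    poor <- cs > theta
    H <- sum(poor) / length(poor)
    A <- if (any(poor)) sum(cs[poor]) / sum(poor) else NA_real_
    out[[cid]] <- data.frame(commune_id = cid, H = H, A = A,
                             MPI = if (any(poor)) H * A else 0)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# brute-force joint-Gaussian conditioning oracle for GP posterior at one
# test point: builds the full (N+1) covariance and conditions explicitly
gp_posterior_oracle <- function(y, X, S, xstar, sstar, params) {
  N <- length(y)
  Xa <- rbind(X, xstar)
  Sa <- rbind(S, sstar)
  Ka <- gp_kernel(Xa, Sa, Xa, Sa, params)
  # joint covariance of (y, y*) includes noise on every component
  Sigma <- Ka + diag(params$sigma_n2, N + 1)
  b <- drop(Xa %*% params$beta)
  S11 <- Sigma[1:N, 1:N]
  S12 <- Sigma[1:N, N + 1]
  mu <- b[N + 1] + drop(t(S12) %*% solve(S11, y - b[1:N]))
  v <- Sigma[N + 1, N + 1] - drop(t(S12) %*% solve(S11, S12))
  c(mean = mu, variance = v)
}
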