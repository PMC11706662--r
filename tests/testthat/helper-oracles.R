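# Independent oracles and small fixture builders. Everything here is a
# second, deliberately different computational route from the package
# implementation it checks.

# --- general (oblique) spherical LAEA forward formula, Snyder form;
#     checks the package's polar-aspect closed form
laea_oracle <- function(lon, lat, lon0 = 45, R = 6371007.181) {
  phi1 <- pi / 2
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  kp <- sqrt(2 / (1 + sin(phi1) * sin(phi) +
                    cos(phi1) * cos(phi) * cos(lam)))
  x <- R * kp * cos(phi) * sin(lam)
  y <- R * kp * (cos(phi1) * sin(phi) - sin(phi1) * cos(phi) * cos(lam))
  cbind(x = x, y = y)
}

# --- brute-force DBSCAN by explicit density-reachability closure:
#     core points from the full distance matrix, clusters as the
#     transitive closure over core-core eps-links, border points claimed
#     by the first cluster in scan order (same semantics, different
#     algorithm/code path from the package's queue-based scan)
dbscan_oracle <- function(xy, eps_m, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nb <- d <= eps_m
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    members <- i
    repeat {
      # all core points eps-linked to current core members
      reach <- which(core & labels == 0L &
                       apply(nb[, members, drop = FALSE], 1, any))
      reach <- setdiff(reach, members)
      if (length(reach) == 0) break
      members <- c(members, reach)
    }
    labels[members] <- cl
  }
  # border points: first claiming cluster in scan order means the cluster
  # of the first core neighbour found when scanning points in order
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cands <- which(nb[i, ] & core)
    if (length(cands) > 0) {
      # the package assigns borders while expanding the earliest cluster
      # that reaches them; equivalently, the smallest label among core
      # neighbours
      labels[i] <- min(labels[cands])
    }
  }
  labels
}

# partitions equal up to relabelling (noise = 0 must coincide exactly)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- a != 0L
  if (!any(ok)) return(TRUE)
  ta <- table(paste(a[ok], b[ok]))
  length(ta) == length(unique(a[ok])) &&
    length(ta) == length(unique(b[ok]))
}

# --- dense multivariate-normal CTCRW log-likelihood (one call covers
#     both axes): build the full joint covariance of observed positions
#     from the state recursion and evaluate the Gaussian log-density
dense_ctcrw_loglik <- function(times, zx, zy, tau2, beta, sigma,
                               pos_var = 1e14) {
  n <- length(times)
  Pk <- vector("list", n)   # marginal state covariance at each time
  P <- matrix(c(pos_var, 0, 0, sigma^2 / (2 * beta)), 2, 2)
  Pk[[1]] <- P
  Phis <- vector("list", n) # transition from k-1 to k
  for (k in 2:n) {
    dt <- times[k] - times[k - 1]
    e1 <- exp(-beta * dt)
    Phi <- matrix(c(1, 0, (1 - e1) / beta, e1), 2, 2)
    qpp <- (sigma^2 / beta^2) *
      (dt - (2 / beta) * (1 - e1) + (1 / (2 * beta)) * (1 - exp(-2 * beta * dt)))
    qvv <- (sigma^2 / (2 * beta)) * (1 - exp(-2 * beta * dt))
    qpv <- (sigma^2 / (2 * beta^2)) * (1 - e1)^2
    Q <- matrix(c(qpp, qpv, qpv, qvv), 2, 2)
    Phis[[k]] <- Phi
    P <- Phi %*% P %*% t(Phi) + Q
    Pk[[k]] <- P
  }
  Sig <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Sig[i, i] <- Pk[[i]][1, 1] + tau2[i]
    if (i < n) {
      Phi_ij <- diag(2)
      for (j in (i + 1):n) {
        Phi_ij <- Phis[[j]] %*% Phi_ij
        cov_ij <- Pk[[i]] %*% t(Phi_ij)
        Sig[i, j] <- Sig[j, i] <- cov_ij[1, 1]
      }
    }
  }
  ch <- chol(Sig)
  logdet <- 2 * sum(log(diag(ch)))
  qf <- function(z) sum(backsolve(ch, z, transpose = TRUE)^2)
  -0.5 * (2 * n * log(2 * pi) + 2 * logdet + qf(zx) + qf(zy))
}

# --- exhaustive minimal-removal speed-filter oracle (tiny n only):
#     smallest subset whose removal leaves no violating segment
speed_filter_oracle <- function(track, vmax_kmh) {
  n <- nrow(track)
  for (k in 0:(n - 2)) {
    combs <- utils::combn(n, k, simplify = FALSE)
    for (rm in combs) {
      sub <- if (k == 0) track else track[-rm, , drop = FALSE]
      if (all(segment_speeds_kmh(sub) <= vmax_kmh))
        return(sort(rm))
    }
  }
  integer(0)
}

# --- fixture builders -------------------------------------------------

# a bare projected track from x/y offsets (metres) around a lon/lat
# anchor, with uniform class and time step
make_track <- function(x, y, dt_h = 1, lc = "3",
                       t0 = as.POSIXct("2022-05-01 00:00:00", tz = "UTC"),
                       anchor = c(60, 65), id = "t1") {
  stopifnot(length(x) == length(y))
  a <- laea_project(anchor[1], anchor[2])
  px <- a[1, "x"] + x
  py <- a[1, "y"] + y
  ll <- laea_unproject(px, py)
  data.frame(id = id,
             timestamp = t0 + seq_along(x) * dt_h * 3600,
             lon = ll[, "lon"], lat = ll[, "lat"],
             lc = lc, error_radius_m = NA_real_, x = px, y = py)
}

# lon/lat track (unprojected) for preprocess tests
make_lonlat_track <- function(lon, lat, dt_h = 1, lc = "3",
                              t0 = as.POSIXct("2022-05-01 00:00:00",
                                              tz = "UTC"), id = "t1") {
  data.frame(id = id, timestamp = t0 + seq_along(lon) * dt_h * 3600,
             lon = lon, lat = lat, lc = lc, error_radius_m = NA_real_)
}

# a noise-free error model (every class sd = 0, no outliers)
zero_noise_model <- function() {
  argos_error_model(class_sd_m = c("3" = 0, "2" = 0, "1" = 0, "0" = 0,
                                   "A" = 0, "B" = 0))
}

# low-noise model for recovery fixtures (all classes sd in metres)
uniform_noise_model <- function(sd_m) {
  argos_error_model(class_sd_m = c("3" = sd_m, "2" = sd_m, "1" = sd_m,
                                   "0" = sd_m, "A" = sd_m, "B" = sd_m))
}

# match detected residency areas to true bouts by interval overlap;
# returns a data.frame of matched pairs with boundary/tenure errors in
# days, using the observable twin of each bout (its first/last fix)
match_areas_to_bouts <- function(areas, itinerary, track) {
  tab <- areas_table(areas)
  bouts <- itinerary$bouts
  ft <- track$timestamp
  rows <- NULL
  for (k in seq_len(nrow(tab))) {
    ov <- pmax(0, as.numeric(
      pmin(tab$departure[k], bouts$end) -
        pmax(tab$arrival[k], bouts$start), units = "secs"))
    b <- which.max(ov)
    if (ov[b] <= 0) next
    inb <- ft >= bouts$start[b] & ft <= bouts$end[b]
    if (!any(inb)) next
    rows <- rbind(rows, data.frame(
      area = k, bout = b,
      arr_err_d = abs(as.numeric(difftime(tab$arrival[k], min(ft[inb]),
                                          units = "days"))),
      dep_err_d = abs(as.numeric(difftime(tab$departure[k], max(ft[inb]),
                                          units = "days"))),
      ten_err_d = abs(tab$tenure_days[k] -
                        as.numeric(difftime(max(ft[inb]), min(ft[inb]),
                                            units = "days")))))
  }
  rows
}

dist_km <- function(p, q) {
  geosphere::distHaversine(p, q, r = 6371000) / 1000
}
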