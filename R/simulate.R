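#' Configuration for the synthetic itinerary generator
#'
#' Describes the study conditions the generator emulates: a breeding
#' season during which an individual alternates multi-day residencies at
#' discrete sites with fast directed transits. Defaults follow the
#' study system: an 11-site season (the observed median number of sites),
#' tenures log-normal with median 2 days, transits at 60 km/h ground
#' speed, sites at least three clustering radii apart inside a
#' north-Eurasian breeding-range box, and a 5% chance that a bout
#' revisits an earlier site.
#'
#' @param season_start,season_end POSIXct UTC season bounds.
#' @param n_sites number of residency bouts K (>= 1).
#' @param region named list with `lon` and `lat` ranges (degrees) from
#'   which site centres are drawn.
#' @param min_separation_m minimum great-circle distance between distinct
#'   site centres (metres); default three times the default clustering
#'   radius of 6600 m.
#' @param hop_median_km,hop_sdlog log-normal distribution of the
#'   great-circle distance between successively visited sites (median in
#'   km; default 210 km, the observed median hop in the study system).
#' @param tenure_median_days,tenure_sdlog log-normal tenure distribution
#'   (median in days, sd on the log scale).
#' @param transit_speed_kmh ground speed during transits.
#' @param revisit_prob per-bout probability (from the third bout on) of
#'   returning to a previously used, non-adjacent site.
#' @return a `sim_config` list.
#' @export
sim_config <- function(season_start = as.POSIXct("2022-04-13 00:00:00",
                                                 tz = "UTC"),
                       season_end = as.POSIXct("2022-07-01 00:00:00",
                                               tz = "UTC"),
                       n_sites = 11,
                       region = list(lon = c(30, 90), lat = c(55, 72)),
                       min_separation_m = 3 * 6600,
                       hop_median_km = 210,
                       hop_sdlog = 1,
                       tenure_median_days = 2,
                       tenure_sdlog = 1,
                       transit_speed_kmh = 60,
                       revisit_prob = 0.05) {
  if (n_sites < 1) stop("invalid config: n_sites must be >= 1")
  if (!is.list(region) || diff(region$lon) <= 0 || diff(region$lat) <= 0)
    stop("invalid config: empty region")
  if (season_end <= season_start) stop("invalid config: empty season")
  if (tenure_median_days <= 0 || transit_speed_kmh <= 0)
    stop("invalid config: non-positive tenure or speed")
  if (revisit_prob < 0 || revisit_prob > 1) stop("invalid revisit_prob")
  if (hop_median_km * 1000 < min_separation_m)
    stop("invalid config: median hop below minimum site separation")
  structure(list(season_start = season_start, season_end = season_end,
                 n_sites = as.integer(n_sites), region = region,
                 min_separation_m = min_separation_m,
                 hop_median_km = hop_median_km, hop_sdlog = hop_sdlog,
                 tenure_median_days = tenure_median_days,
                 tenure_sdlog = tenure_sdlog,
                 transit_speed_kmh = transit_speed_kmh,
                 revisit_prob = revisit_prob),
            class = "sim_config")
}

#' Simulate a ground-truth nomadic itinerary
#'
#' Generates K residency bouts at discrete sites, connected by
#' great-circle transits at constant ground speed, tiling the season
#' exactly: log-normal tenure draws are rescaled so that bouts plus
#' transits fill the window. A bout may revisit an earlier (non-adjacent)
#' site with probability `revisit_prob`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical (config, seed) gives identical
#'   itineraries.
#' @param individual_id id string recorded in the itinerary.
#' @return a `true_itinerary` list with elements `individual_id`, `sites`
#'   (data.frame site_id, lon, lat), `bouts` (site_id, start, end),
#'   `transits` (from_site, to_site, departure, arrival) and
#'   `revisited_site_ids`.
#' @export
simulate_itinerary <- function(config, seed, individual_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  K <- config$n_sites

  # site centres: an itinerant progression — each site a log-normal hop
  # from the previous one, kept inside the region and pairwise separated
  in_region <- function(p) {
    p[1] >= config$region$lon[1] && p[1] <= config$region$lon[2] &&
      p[2] >= config$region$lat[1] && p[2] <= config$region$lat[2]
  }
  start <- c(stats::runif(1, config$region$lon[1], config$region$lon[2]),
             stats::runif(1, config$region$lat[1], config$region$lat[2]))
  centres <- matrix(start, ncol = 2)
  tries <- 0
  while (nrow(centres) < K) {
    hop_m <- 1000 * stats::rlnorm(1, log(config$hop_median_km),
                                  config$hop_sdlog)
    brg <- stats::runif(1, 0, 360)
    cand <- as.numeric(geosphere::destPoint(centres[nrow(centres), ], brg,
                                            max(hop_m,
                                                config$min_separation_m),
                                            a = 6371000, f = 0))
    ok <- in_region(cand) &&
      all(geosphere::distHaversine(cand, centres, r = 6371000) >=
            config$min_separation_m)
    if (ok) centres <- rbind(centres, cand)
    tries <- tries + 1
    if (tries > 2000 * K)
      stop("invalid config: region too small for requested site separation")
  }
  sites <- data.frame(site_id = seq_len(K),
                      lon = centres[, 1], lat = centres[, 2])

  # bout -> site assignment, with optional revisits of earlier sites
  bout_site <- integer(K)
  nxt <- 1
  for (b in seq_len(K)) {
    prev_sites <- unique(bout_site[seq_len(b - 1)])
    candidates <- setdiff(prev_sites, bout_site[b - 1])
    if (b >= 3 && length(candidates) > 0 &&
        stats::runif(1) < config$revisit_prob) {
      bout_site[b] <- candidates[sample.int(length(candidates), 1)]
    } else {
      bout_site[b] <- nxt
      nxt <- nxt + 1
    }
  }

  # transit durations follow from geometry and speed; tenures are
  # log-normal draws (median as configured). Bouts and transits abut
  # without gaps from the season start; an itinerary overrunning the
  # season end is truncated there (the final bout clipped, later bouts
  # dropped), so the realised itinerary tiles its own tracked span.
  trans_km <- numeric(max(K - 1, 0))
  for (b in seq_len(max(K - 1, 0))) {
    trans_km[b] <- geosphere::distHaversine(
      unlist(sites[sites$site_id == bout_site[b], c("lon", "lat")]),
      unlist(sites[sites$site_id == bout_site[b + 1], c("lon", "lat")]),
      r = 6371000) / 1000
  }
  trans_days <- trans_km / config$transit_speed_kmh / 24
  tenures <- stats::rlnorm(K, meanlog = log(config$tenure_median_days),
                           sdlog = config$tenure_sdlog)

  starts <- ends <- rep(config$season_start, K)
  dep <- arr <- rep(config$season_start, max(K - 1, 0))
  t0 <- config$season_start
  n_kept <- K
  for (b in seq_len(K)) {
    starts[b] <- t0
    ends[b] <- min(t0 + tenures[b] * 86400, config$season_end)
    if (as.numeric(ends[b]) - as.numeric(starts[b]) <= 0) {
      n_kept <- b - 1L
      break
    }
    t0 <- ends[b]
    if (b < K) {
      dep[b] <- t0
      arr[b] <- t0 + trans_days[b] * 86400
      t0 <- arr[b]
      if (arr[b] >= config$season_end) {
        n_kept <- b
        break
      }
    }
  }
  if (n_kept < 1) stop("invalid config: season too short for one bout")
  bout_site <- bout_site[seq_len(n_kept)]
  used <- sort(unique(bout_site))
  sites <- sites[sites$site_id %in% used, , drop = FALSE]
  bouts <- data.frame(site_id = bout_site,
                      start = starts[seq_len(n_kept)],
                      end = ends[seq_len(n_kept)])
  transits <- if (n_kept > 1) {
    data.frame(from_site = bout_site[-n_kept], to_site = bout_site[-1],
               departure = dep[seq_len(n_kept - 1)],
               arrival = arr[seq_len(n_kept - 1)])
  } else {
    data.frame(from_site = integer(0), to_site = integer(0),
               departure = starts[0], arrival = starts[0])
  }
  revisited <- as.integer(names(which(table(bout_site) >= 2)))
  structure(list(individual_id = individual_id, sites = sites,
                 bouts = bouts, transits = transits,
                 revisited_site_ids = revisited, config = config),
            class = "true_itinerary")
}

#' True position (lon/lat) on an itinerary path at given times
#'
#' During a bout the individual sits at the site centre; during a transit
#' it moves along the great circle between centres at constant speed.
#'
#' @param itinerary a `true_itinerary`.
#' @param times POSIXct vector within the season.
#' @return n x 2 matrix of lon/lat degrees.
#' @export
itinerary_position <- function(itinerary, times) {
  sites <- itinerary$sites
  bouts <- itinerary$bouts
  trans <- itinerary$transits
  out <- matrix(NA_real_, nrow = length(times), ncol = 2,
                dimnames = list(NULL, c("lon", "lat")))
  site_xy <- function(id) unlist(sites[sites$site_id == id,
                                       c("lon", "lat")], use.names = FALSE)
  for (i in seq_along(times)) {
    tt <- times[i]
    b <- which(bouts$start <= tt & tt <= bouts$end)
    if (length(b) > 0) {
      out[i, ] <- site_xy(bouts$site_id[b[1]])
      next
    }
    k <- which(trans$departure < tt & tt < trans$arrival)
    if (length(k) == 1) {
      frac <- as.numeric(difftime(tt, trans$departure[k], units = "secs")) /
        as.numeric(difftime(trans$arrival[k], trans$departure[k],
                            units = "secs"))
      p1 <- site_xy(trans$from_site[k])
      p2 <- site_xy(trans$to_site[k])
      d <- geosphere::distHaversine(p1, p2, r = 6371000)
      brg <- geosphere::bearing(p1, p2, a = 6371000, f = 0)
      out[i, ] <- geosphere::destPoint(p1, brg, frac * d, a = 6371000, f = 0)
    }
  }
  out
}

#' Configuration of the Argos sampling scheme
#'
#' Duty-cycled sampling: fixes every `fix_interval_h` hours while the tag
#' transmits, in on/off cycles of `duty_on_h` transmitting hours followed
#' by `duty_off_h` silent hours, with small uniform timing jitter.
#' Defaults emulate a solar Argos transmitter at high latitude in the
#' continuous daylight of the boreal breeding season: satellite passes
#' every ~15 min and a long 16 h-on / 8 h-off duty cycle.
#'
#' @param fix_interval_h mean interval between fixes while on (hours).
#' @param duty_on_h,duty_off_h duty-cycle structure (hours).
#' @param jitter_frac uniform timing jitter as a fraction of the interval.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(fix_interval_h = 0.25, duty_on_h = 16,
                            duty_off_h = 8, jitter_frac = 0.2) {
  if (fix_interval_h <= 0) stop("invalid config: non-positive fix interval")
  if (duty_on_h <= 0 || duty_off_h < 0) stop("invalid duty cycle")
  structure(list(fix_interval_h = fix_interval_h, duty_on_h = duty_on_h,
                 duty_off_h = duty_off_h, jitter_frac = jitter_frac),
            class = "sampling_config")
}

#' Simulate Argos-like observations of an itinerary
#'
#' Samples fix times on the duty cycle, evaluates the true path, draws an
#' Argos class i.i.d. from the error model's class probabilities, and
#' perturbs the projected true position by zero-mean isotropic Gaussian
#' noise with the class sd (or the outlier sd, with probability
#' `outlier_prob`). The error radius column is filled with the class's
#' nominal radius for classes 3/2/1/0 and left missing for A/B.
#'
#' @param itinerary a `true_itinerary` (may be NULL for an empty track).
#' @param error_model an [argos_error_model()].
#' @param sampling a [sampling_config()].
#' @param seed integer seed.
#' @return a track data.frame: id, timestamp, lon, lat, lc,
#'   error_radius_m, plus logical `is_outlier` (simulation truth, not part
#'   of the CSV dialect).
#' @export
simulate_argos_observations <- function(itinerary, error_model, sampling,
                                        seed) {
  stopifnot(inherits(error_model, "argos_error_model"),
            inherits(sampling, "sampling_config"))
  empty <- data.frame(id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      lon = numeric(0), lat = numeric(0),
                      lc = character(0), error_radius_m = numeric(0),
                      is_outlier = logical(0))
  if (is.null(itinerary)) return(empty)
  stopifnot(inherits(itinerary, "true_itinerary"))
  set.seed(as.integer(seed))

  t0 <- itinerary$bouts$start[1]
  t1 <- itinerary$bouts$end[nrow(itinerary$bouts)]
  span_h <- as.numeric(difftime(t1, t0, units = "hours"))
  cycle <- sampling$duty_on_h + sampling$duty_off_h
  cand <- seq(0, span_h, by = sampling$fix_interval_h)
  cand <- cand[cand %% cycle < sampling$duty_on_h]
  if (length(cand) == 0) return(empty)
  jit <- stats::runif(length(cand), -1, 1) *
    sampling$jitter_frac * sampling$fix_interval_h
  times <- t0 + sort(cand + jit) * 3600
  times <- times[times >= t0 & times <= t1]
  times <- times[!duplicated(round(as.numeric(times)))]

  true_ll <- itinerary_position(itinerary, times)
  keep <- stats::complete.cases(true_ll)
  times <- times[keep]
  true_ll <- true_ll[keep, , drop = FALSE]
  n <- nrow(true_ll)

  lc <- sample(ARGOS_CLASSES, n, replace = TRUE,
               prob = error_model$class_probs)
  sd_m <- unname(error_model$class_sd_m[lc])
  is_outlier <- stats::runif(n) < error_model$outlier_prob
  sd_m[is_outlier] <- error_model$outlier_sd_m

  xy <- laea_project(true_ll[, "lon"], true_ll[, "lat"])
  xy[, 1] <- xy[, 1] + stats::rnorm(n, 0, sd_m)
  xy[, 2] <- xy[, 2] + stats::rnorm(n, 0, sd_m)
  ll <- laea_unproject(xy[, 1], xy[, 2])

  radius <- ifelse(lc %in% c("A", "B"), NA_real_,
                   unname(error_model$class_sd_m[lc]))
  data.frame(id = itinerary$individual_id, timestamp = times,
             lon = ll[, "lon"], lat = ll[, "lat"], lc = lc,
             error_radius_m = radius, is_outlier = is_outlier)
}

#' Write a track to the pipeline CSV dialect
#'
#' Columns `id,timestamp,lon,lat,lc,error_radius_m`, timestamps ISO-8601
#' UTC; the error radius is empty for classes A/B.
#' @param track track data.frame.
#' @param path output file.
#' @export
write_track_csv <- function(track, path) {
  out <- data.frame(
    id = track$id,
    timestamp = format(track$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lon = sprintf("%.8f", track$lon),
    lat = sprintf("%.8f", track$lat),
    lc = track$lc,
    error_radius_m = ifelse(is.na(track$error_radius_m), "",
                            sprintf("%.1f", track$error_radius_m)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a ground-truth itinerary JSON sidecar
#' @param itinerary a `true_itinerary`.
#' @param path file path.
#' @export
write_itinerary_json <- function(itinerary, path) {
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  obj <- list(individual_id = itinerary$individual_id,
              sites = itinerary$sites,
              bouts = data.frame(site_id = itinerary$bouts$site_id,
                                 start = fmt(itinerary$bouts$start),
                                 end = fmt(itinerary$bouts$end)),
              transits = if (nrow(itinerary$transits) > 0)
                data.frame(from_site = itinerary$transits$from_site,
                           to_site = itinerary$transits$to_site,
                           departure = fmt(itinerary$transits$departure),
                           arrival = fmt(itinerary$transits$arrival))
              else list(),
              revisited_site_ids = itinerary$revisited_site_ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_itinerary_json
#' @export
read_itinerary_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_t <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC")
  obj$bouts$start <- parse_t(obj$bouts$start)
  obj$bouts$end <- parse_t(obj$bouts$end)
  if (length(obj$transits) > 0 && !is.null(nrow(obj$transits))) {
    obj$transits$departure <- parse_t(obj$transits$departure)
    obj$transits$arrival <- parse_t(obj$transits$arrival)
  } else {
    obj$transits <- data.frame(from_site = integer(0), to_site = integer(0),
                               departure = parse_t(character(0)),
                               arrival = parse_t(character(0)))
  }
  obj$revisited_site_ids <- as.integer(obj$revisited_site_ids)
  structure(obj, class = "true_itinerary")
}
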