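#' Detect revisited residency areas by convex-hull overlap
#'
#' For every ordered pair of areas the overlap fraction is the
#' intersection area divided by the smaller hull's area; a later area is
#' a revisit of the earlier one when the fraction is strictly greater
#' than 0.5. Each later area counts as at most one revisit, attributed to
#' the earlier area with the maximal overlap.
#'
#' @param areas a `residency_areas` object, time-ordered.
#' @return data.frame: earlier_id, later_id, overlap_fraction, is_revisit.
#' @export
detect_revisits <- function(areas) {
  n <- length(areas)
  empty <- data.frame(earlier_id = integer(0), later_id = integer(0),
                      overlap_fraction = numeric(0), is_revisit = logical(0))
  if (n < 2) return(empty)
  rows <- list()
  for (j in 2:n) {
    ov <- vapply(seq_len(j - 1), function(i)
      hull_overlap_fraction(areas[[i]]$hull, areas[[j]]$hull), numeric(1))
    best <- which.max(ov)
    for (i in seq_len(j - 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        earlier_id = areas[[i]]$area_id,
        later_id = areas[[j]]$area_id,
        overlap_fraction = ov[i],
        is_revisit = (i == best) && ov[i] > 0.5)
    }
  }
  do.call(rbind, rows)
}

#' Angular variance of bearings between successive sites
#'
#' Initial great-circle bearings between successive site centroids,
#' summarised as 1 minus the mean resultant length of the unit bearing
#' vectors: 0 when all bearings coincide, 1 when they cancel completely.
#'
#' @param centroids matrix or data.frame with columns lon, lat, in visit
#'   order (>= 2 rows).
#' @return angular variance in [0, 1], or NA for fewer than 2 sites.
#' @export
bearing_variance <- function(centroids) {
  centroids <- as.matrix(centroids)[, c("lon", "lat"), drop = FALSE]
  n <- nrow(centroids)
  if (n < 2) return(NA_real_)
  b <- geosphere::bearing(centroids[-n, , drop = FALSE],
                          centroids[-1, , drop = FALSE],
                          a = EARTH_RADIUS_M, f = 0) * pi / 180
  rbar <- sqrt(mean(cos(b))^2 + mean(sin(b))^2)
  1 - rbar
}

#' Per-individual behavioural summary
#'
#' The variables describing one individual's breeding-site sampling:
#' number of sites, site visitation rate per week, total distance along
#' the predicted track, between-site (centroid hop) distances, percent
#' of tracked time spent travelling, mean and maximum tenure, revisits
#' (>50% hull overlap), and the bearing variance and mean tenure before
#' versus after the longest-tenure site (that site itself excluded from
#' both periods; ties for longest tenure go to the earliest arrival).
#'
#' @param areas `residency_areas` for the individual.
#' @param transits output of [extract_transits()].
#' @param regular the individual's `regular_track`.
#' @return one-row data.frame (`sampling_summary`).
#' @export
summarize_individual <- function(areas, transits, regular) {
  id <- if (nrow(regular) > 0) regular$id[1] else NA_character_
  span_days <- if (nrow(regular) > 1)
    as.numeric(difftime(regular$timestamp[nrow(regular)],
                        regular$timestamp[1], units = "days")) else 0
  total_km <- 0
  if (nrow(regular) > 1) {
    p <- cbind(regular$lon, regular$lat)
    total_km <- sum(geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                             p[-1, , drop = FALSE],
                                             r = EARTH_RADIUS_M)) / 1000
  }
  transit_days <- sum(vapply(transits, `[[`, numeric(1), "duration_days"))
  pct_travel <- if (span_days > 0) 100 * transit_days / span_days else NA_real_

  n_sites <- length(areas)
  base <- data.frame(id = id, n_sites = n_sites,
                     sites_per_week = if (span_days > 0)
                       n_sites / (span_days / 7) else NA_real_,
                     total_distance_km = total_km,
                     sum_between_site_km = NA_real_,
                     median_between_site_km = NA_real_,
                     pct_time_travelling = pct_travel,
                     mean_tenure_days = NA_real_,
                     max_tenure_days = NA_real_,
                     n_revisits = NA_integer_,
                     revisit_probability = NA_real_,
                     longest_tenure_area_id = NA_integer_,
                     bearing_variance = NA_real_,
                     bearing_variance_before = NA_real_,
                     bearing_variance_after = NA_real_,
                     mean_tenure_before = NA_real_,
                     mean_tenure_after = NA_real_,
                     tracked_days = span_days)
  if (n_sites == 0) {
    class(base) <- c("sampling_summary", "data.frame")
    return(base)
  }

  tenures <- vapply(areas, `[[`, numeric(1), "tenure_days")
  cent <- data.frame(
    lon = vapply(areas, `[[`, numeric(1), "centroid_lon"),
    lat = vapply(areas, `[[`, numeric(1), "centroid_lat"))
  between_km <- numeric(0)
  if (n_sites >= 2) {
    p <- as.matrix(cent)
    between_km <- geosphere::distHaversine(p[-n_sites, , drop = FALSE],
                                           p[-1, , drop = FALSE],
                                           r = EARTH_RADIUS_M) / 1000
  }
  rev_pairs <- detect_revisits(areas)
  n_rev <- sum(rev_pairs$is_revisit)

  longest <- which(tenures == max(tenures))[1] # earliest on ties
  before <- seq_len(n_sites) < longest
  after <- seq_len(n_sites) > longest

  base$sum_between_site_km <- sum(between_km)
  base$median_between_site_km <- if (length(between_km) > 0)
    stats::median(between_km) else NA_real_
  base$mean_tenure_days <- mean(tenures)
  base$max_tenure_days <- max(tenures)
  base$n_revisits <- n_rev
  base$revisit_probability <- n_rev / n_sites
  base$longest_tenure_area_id <- areas[[longest]]$area_id
  base$bearing_variance <- if (n_sites >= 2)
    bearing_variance(cent) else NA_real_
  base$bearing_variance_before <- if (sum(before) >= 2)
    bearing_variance(cent[before, , drop = FALSE]) else NA_real_
  base$bearing_variance_after <- if (sum(after) >= 2)
    bearing_variance(cent[after, , drop = FALSE]) else NA_real_
  base$mean_tenure_before <- if (any(before))
    mean(tenures[before]) else NA_real_
  base$mean_tenure_after <- if (any(after))
    mean(tenures[after]) else NA_real_
  class(base) <- c("sampling_summary", "data.frame")
  base
}

#' Paired before/after contrast across individuals
#'
#' Tests whether a behavioural variable differs before versus after the
#' longest-tenure site, with a sign-flip permutation test of the mean
#' within-individual difference (after minus before). Individuals missing
#' either period are dropped. All 2^n sign patterns are enumerated when
#' feasible; otherwise `n_perm` random flips are drawn (the observed
#' pattern always included).
#'
#' @param summaries data.frame of [summarize_individual()] rows.
#' @param variable "bearing_variance" or "mean_tenure".
#' @param n_perm Monte-Carlo permutations when exhaustive enumeration
#'   exceeds this count (default 10000).
#' @param seed seed for the Monte-Carlo branch.
#' @return one-row data.frame: variable, n, mean_before, mean_after,
#'   mean_difference, p_value, exhaustive.
#' @export
before_after_contrast <- function(summaries, variable = "bearing_variance",
                                  n_perm = 10000, seed = 1) {
  bcol <- paste0(variable, "_before")
  acol <- paste0(variable, "_after")
  if (!all(c(bcol, acol) %in% names(summaries)))
    stop("unknown variable: ", variable)
  ok <- stats::complete.cases(summaries[, c(bcol, acol)])
  if (sum(!ok) > 0)
    message(sum(!ok), " individual(s) lacking one period excluded")
  b <- summaries[[bcol]][ok]
  a <- summaries[[acol]][ok]
  n <- length(b)
  if (n < 2) stop("need >= 2 individuals with both periods")
  d <- a - b
  obs <- mean(d)
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(signs %*% d) / n
    p <- mean(stat >= abs(obs) - 1e-12)
    exhaustive <- TRUE
  } else {
    set.seed(as.integer(seed))
    stat <- replicate(n_perm, abs(mean(d * sample(c(-1, 1), n,
                                                  replace = TRUE))))
    p <- (sum(stat >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
    exhaustive <- FALSE
  }
  data.frame(variable = variable, n = n, mean_before = mean(b),
             mean_after = mean(a), mean_difference = obs, p_value = p,
             exhaustive = exhaustive)
}
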