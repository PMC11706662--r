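#' Clustering parameters for residency-area detection
#'
#' Defaults are the published starting values for this study system:
#' MinPts = 8 fixes, radius eps = 6.6 km, maxLag = 10 fixes. Per-individual
#' overrides (the study mostly settled on eps = 5 km and maxLag = 16 after
#' visual inspection) can be supplied through [run_config()].
#'
#' @param min_pts minimum number of fixes (including the point itself)
#'   within `eps_m` for a core point; also the minimum residency-area size.
#' @param eps_m neighbourhood radius in projected metres.
#' @param max_lag maximum separation, in positions of the full
#'   time-ordered track, across which two memberships of the same spatial
#'   cluster still count as one visit.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(min_pts = 8, eps_m = 6600, max_lag = 10) {
  if (min_pts < 2) stop("min_pts must be >= 2")
  if (eps_m <= 0) stop("eps_m must be positive")
  if (max_lag < 1) stop("max_lag must be >= 1")
  structure(list(min_pts = as.integer(min_pts), eps_m = eps_m,
                 max_lag = as.integer(max_lag)), class = "cluster_params")
}

#' Density-based spatial clustering (DBSCAN) on projected points
#'
#' Standard DBSCAN semantics: a core point has at least `min_pts`
#' neighbours (itself included) within `eps_m`; clusters are maximal
#' density-connected sets of core points plus their border points. Border
#' points reachable from several clusters are assigned to the first
#' claiming cluster in scan order, so labels are deterministic for a
#' given input order. Non-reachable points are labelled 0 (noise).
#'
#' @param xy n x 2 matrix of projected coordinates (metres).
#' @param eps_m neighbourhood radius (metres).
#' @param min_pts core-point threshold.
#' @return integer vector of cluster labels (0 = noise).
#' @export
dbscan_labels <- function(xy, eps_m, min_pts) {
  if (!is.matrix(xy)) xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  if (any(!is.finite(xy))) stop("non-finite coordinates")
  d2 <- as.matrix(stats::dist(xy))^2
  eps2 <- eps_m^2
  nbrs <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Split a spatial cluster into temporally contiguous visits
#'
#' Builds the temporal-contiguity graph of one cluster: vertices are the
#' cluster's member fixes, and temporally consecutive members are joined
#' by an edge whose lag is their separation in the individual's full
#' time-ordered track. Edges with lag greater than `max_lag` are dropped
#' (the animal demonstrably recorded more than `max_lag` positions
#' elsewhere in between), and the connected components of the remaining
#' graph are the distinct visits. The lag threshold is inclusive: a gap
#' of exactly `max_lag` does not split.
#'
#' @param member_idx integer positions of the cluster's members in the
#'   full time-ordered track, sorted.
#' @param max_lag inclusive lag threshold.
#' @return list of integer vectors (time-ordered member positions), in
#'   order of first appearance.
#' @export
temporal_split <- function(member_idx, max_lag) {
  m <- length(member_idx)
  if (m == 0) return(list())
  member_idx <- sort(member_idx)
  if (m == 1) return(list(member_idx))
  lag <- diff(member_idx)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  keep <- which(lag <= max_lag)
  if (length(keep) > 0)
    g <- igraph::add_edges(g, rbind(keep, keep + 1L))
  comp <- igraph::components(g)$membership
  unname(split(member_idx, comp))
}

#' Identify residency areas in a projected track
#'
#' The full procedure: DBSCAN on the projected fixes, temporal-contiguity
#' split of each spatial cluster, then DBSCAN re-run within every
#' temporal component with the same parameters to confirm its density
#' (components whose re-clustered core falls below `min_pts` are demoted
#' to noise). Each surviving visit becomes a residency area with arrival
#' (earliest member fix), departure (latest), tenure in days, the convex
#' hull of its member projected points (degenerate hulls buffered by
#' 1 m), and the centroid (mean of member coordinates, reported in
#' lon/lat). Areas are returned ordered by arrival time.
#'
#' @param track projected, filtered track data.frame (columns x, y,
#'   timestamp).
#' @param params a [cluster_params()].
#' @return a `residency_areas` object: list of areas, each with
#'   `area_id`, `members`, `arrival`, `departure`, `tenure_days`, `hull`,
#'   `centroid_lon`, `centroid_lat`, `n_fixes`.
#' @export
find_residency_areas <- function(track, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (nrow(track) == 0)
    return(structure(list(), class = "residency_areas"))
  xy <- cbind(track$x, track$y)
  labels <- dbscan_labels(xy, params$eps_m, params$min_pts)
  visits <- list()
  for (cl in setdiff(sort(unique(labels)), 0L)) {
    members <- which(labels == cl)
    for (comp in temporal_split(members, params$max_lag)) {
      if (length(comp) < params$min_pts) next
      sub_labels <- dbscan_labels(xy[comp, , drop = FALSE],
                                  params$eps_m, params$min_pts)
      for (scl in setdiff(sort(unique(sub_labels)), 0L)) {
        sub <- comp[sub_labels == scl]
        if (length(sub) >= params$min_pts)
          visits[[length(visits) + 1L]] <- sub
      }
    }
  }
  if (length(visits) == 0)
    return(structure(list(), class = "residency_areas"))
  arrivals <- vapply(visits, function(v) min(as.numeric(track$timestamp[v])),
                     numeric(1))
  visits <- visits[order(arrivals)]
  areas <- lapply(seq_along(visits), function(k) {
    v <- visits[[k]]
    arr <- min(track$timestamp[v])
    dep <- max(track$timestamp[v])
    cx <- mean(track$x[v])
    cy <- mean(track$y[v])
    ll <- laea_unproject(cx, cy)
    list(area_id = k,
         members = v,
         arrival = arr,
         departure = dep,
         tenure_days = as.numeric(difftime(dep, arr, units = "days")),
         hull = convex_hull_poly(xy[v, , drop = FALSE]),
         centroid_lon = unname(ll[1, "lon"]),
         centroid_lat = unname(ll[1, "lat"]),
         n_fixes = length(v))
  })
  structure(areas, class = "residency_areas")
}

#' Residency areas as a data.frame (one row per area)
#' @param areas a `residency_areas` object.
#' @param id individual id recorded in the table.
#' @return data.frame with arrival, departure, tenure, centroid, size.
#' @export
areas_table <- function(areas, id = NA_character_) {
  if (length(areas) == 0)
    return(data.frame(id = character(0), area_id = integer(0),
                      arrival = as.POSIXct(character(0), tz = "UTC"),
                      departure = as.POSIXct(character(0), tz = "UTC"),
                      tenure_days = numeric(0), centroid_lon = numeric(0),
                      centroid_lat = numeric(0), n_fixes = integer(0)))
  data.frame(id = id,
             area_id = vapply(areas, `[[`, integer(1), "area_id"),
             arrival = as.POSIXct(vapply(areas, function(a)
               as.numeric(a$arrival), numeric(1)), tz = "UTC",
               origin = "1970-01-01"),
             departure = as.POSIXct(vapply(areas, function(a)
               as.numeric(a$departure), numeric(1)), tz = "UTC",
               origin = "1970-01-01"),
             tenure_days = vapply(areas, `[[`, numeric(1), "tenure_days"),
             centroid_lon = vapply(areas, `[[`, numeric(1), "centroid_lon"),
             centroid_lat = vapply(areas, `[[`, numeric(1), "centroid_lat"),
             n_fixes = vapply(areas, `[[`, integer(1), "n_fixes"))
}
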