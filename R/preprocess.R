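EARTH_RADIUS_M <- 6371000 # spherical radius used for all great-circle math

#' Read tracks from the pipeline CSV dialect
#'
#' Expects a header `id,timestamp,lon,lat,lc,error_radius_m` with
#' ISO-8601 UTC timestamps. Fixes are sorted in time per individual;
#' duplicated timestamps keep the fix with the better Argos class
#' (3 > 2 > 1 > 0 > A > B).
#'
#' @param path CSV file.
#' @return named list of track data.frames, one per individual.
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         comment.char = "#")
  need <- c("id", "timestamp", "lon", "lat", "lc", "error_radius_m")
  if (!all(need %in% names(raw)))
    stop("header must contain: ", paste(need, collapse = ","))
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- which(is.na(ts) | is.na(lon) | is.na(lat) |
                 abs(lon) > 180 | abs(lat) > 90)
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1] + 1L)
  if (!all(raw$lc %in% ARGOS_CLASSES))
    stop("unknown Argos class at line ",
         which(!raw$lc %in% ARGOS_CLASSES)[1] + 1L)
  radius <- suppressWarnings(as.numeric(raw$error_radius_m))
  df <- data.frame(id = raw$id, timestamp = ts, lon = lon, lat = lat,
                   lc = raw$lc, error_radius_m = radius)
  lapply(split(df, df$id), function(tr) {
    tr <- tr[order(tr$timestamp,
                   match(tr$lc, ARGOS_CLASSES)), , drop = FALSE]
    dup <- duplicated(tr$timestamp)
    if (any(dup))
      message(sum(dup), " duplicate timestamp(s) dropped for ", tr$id[1],
              " (better class kept)")
    tr <- tr[!dup, , drop = FALSE]
    rownames(tr) <- NULL
    tr
  })
}

#' Project a track to polar Lambert azimuthal equal-area coordinates
#'
#' Adds `x`, `y` columns in metres (central meridian 45E, north-polar
#' aspect); see [laea_project()].
#' @param track track data.frame with lon/lat.
#' @return the track with x, y columns.
#' @export
project_track <- function(track) {
  xy <- laea_project(track$lon, track$lat)
  track$x <- xy[, "x"]
  track$y <- xy[, "y"]
  track
}

#' Breeding-season window
#'
#' Month-day bounds applied to every tracked year; defaults 13 April to
#' 1 July, the interval from a week before the first known nest
#' initiation to the last. Both endpoints are inclusive.
#' @param start,end strings "MM-DD".
#' @return a `season_window`.
#' @export
season_window <- function(start = "04-13", end = "07-01") {
  s <- as.Date(paste0("2000-", start))
  e <- as.Date(paste0("2000-", end))
  if (is.na(s) || is.na(e) || s >= e) stop("invalid season window")
  structure(list(start = start, end = end), class = "season_window")
}

#' Clip a track to the breeding season
#'
#' Retains fixes whose UTC date falls inside the window, endpoints
#' included.
#' @param track track data.frame.
#' @param window a [season_window()].
#' @return the clipped track (possibly empty).
#' @export
clip_season <- function(track, window = season_window()) {
  stopifnot(inherits(window, "season_window"))
  if (nrow(track) == 0) return(track)
  md <- format(track$timestamp, "%m-%d", tz = "UTC")
  keep <- md >= window$start & md <= window$end
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Great-circle speeds (km/h) between consecutive fixes
#' @param track track data.frame (time-ordered).
#' @return numeric vector of length nrow(track) - 1.
#' @export
segment_speeds_kmh <- function(track) {
  n <- nrow(track)
  if (n < 2) return(numeric(0))
  p <- cbind(track$lon, track$lat)
  d_km <- geosphere::distHaversine(p[-n, , drop = FALSE],
                                   p[-1, , drop = FALSE],
                                   r = EARTH_RADIUS_M) / 1000
  dt_h <- diff(as.numeric(track$timestamp)) / 3600
  d_km / dt_h
}

#' Remove implausible fixes with an iterative speed filter
#'
#' Repeatedly removes the fix whose removal most reduces the number of
#' consecutive-fix segments implying a ground speed above `vmax_kmh`,
#' until no segment violates the threshold (McConnell-style worst
#' offender removal). Ties are broken by removing the later fix, making
#' the filter deterministic. Speeds are great-circle on a sphere of
#' radius 6371 km.
#'
#' @param track time-ordered track data.frame.
#' @param vmax_kmh maximum plausible ground speed (default 150 km/h).
#' @return list with `track` (retained fixes) and `removed` (original row
#'   indices of removed fixes).
#' @export
speed_filter <- function(track, vmax_kmh = 150) {
  if (vmax_kmh <= 0) stop("vmax_kmh must be positive")
  n <- nrow(track)
  if (n < 2) return(list(track = track, removed = integer(0)))
  if (any(diff(as.numeric(track$timestamp)) <= 0))
    stop("timestamps must be strictly increasing")
  keep <- seq_len(n)
  repeat {
    sub <- track[keep, , drop = FALSE]
    sp <- segment_speeds_kmh(sub)
    viol <- which(sp > vmax_kmh)
    if (length(viol) == 0) break
    # candidate fixes: endpoints of violating segments
    cand <- sort(unique(c(viol, viol + 1L)))
    best_i <- NA_integer_
    best_nv <- Inf
    for (i in cand) {
      sp2 <- segment_speeds_kmh(sub[-i, , drop = FALSE])
      nv <- sum(sp2 > vmax_kmh)
      # equal violation counts: prefer the later fix (deterministic tie rule)
      if (nv < best_nv || (nv == best_nv && i > best_i)) {
        best_nv <- nv
        best_i <- i
      }
    }
    keep <- keep[-best_i]
    if (length(keep) < 2) break
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(track = out, removed = setdiff(seq_len(n), keep))
}
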