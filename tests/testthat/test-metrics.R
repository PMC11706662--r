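# build a synthetic residency_areas object from site centres (lon/lat),
# tenures (days) and hull radius (m); arrivals spaced daily
make_areas <- function(centroids, tenures = NULL, hull_r = 2000,
                       t0 = as.POSIXct("2022-05-01", tz = "UTC"),
                       gap_days = 1) {
  n <- nrow(centroids)
  if (is.null(tenures)) tenures <- rep(0.5, n)
  t <- t0
  areas <- vector("list", n)
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  for (k in seq_len(n)) {
    xy <- laea_project(centroids[k, 1], centroids[k, 2])
    hull <- cbind(x = xy[1, "x"] + hull_r * cos(ang),
                  y = xy[1, "y"] + hull_r * sin(ang))
    arr <- t
    dep <- t + tenures[k] * 86400
    areas[[k]] <- list(area_id = k, members = integer(0), arrival = arr,
                       departure = dep, tenure_days = tenures[k],
                       hull = convex_hull_poly(hull),
                       centroid_lon = centroids[k, 1],
                       centroid_lat = centroids[k, 2],
                       n_fixes = 8L)
    t <- dep + gap_days * 86400
  }
  structure(areas, class = "residency_areas")
}

test_that("hull overlap classifies revisits with a strict 50% rule", {
  sqr <- function(x0) cbind(x = x0 + c(0, 1000, 1000, 0),
                            y = c(0, 0, 1000, 1000))
  area <- function(id, hull) list(area_id = id, hull = hull,
                                  arrival = Sys.time(), tenure_days = 1)
  mk <- function(...) structure(list(...), class = "residency_areas")
  # identical hulls: overlap 1, revisit
  rv <- detect_revisits(mk(area(1L, sqr(0)), area(2L, sqr(0))))
  expect_equal(rv$overlap_fraction, 1)
  expect_true(rv$is_revisit)
  # disjoint: overlap 0, no revisit
  rv <- detect_revisits(mk(area(1L, sqr(0)), area(2L, sqr(5000))))
  expect_equal(rv$overlap_fraction, 0)
  expect_false(rv$is_revisit)
  # exactly half shared: NOT a revisit (strict >)
  rv <- detect_revisits(mk(area(1L, sqr(0)), area(2L, sqr(500))))
  expect_equal(rv$overlap_fraction, 0.5, tolerance = 1e-9)
  expect_false(rv$is_revisit)
})

test_that("a later area counts as one revisit of its best-overlapping earlier area", {
  sqr <- function(x0) cbind(x = x0 + c(0, 1000, 1000, 0),
                            y = c(0, 0, 1000, 1000))
  area <- function(id, hull) list(area_id = id, hull = hull)
  ar <- structure(list(area(1L, sqr(0)), area(2L, sqr(50)),
                       area(3L, sqr(100))), class = "residency_areas")
  rv <- detect_revisits(ar)
  # area 3 overlaps both earlier areas > 0.5 but is attributed once
  expect_equal(sum(rv$is_revisit[rv$later_id == 3]), 1)
  expect_equal(rv$earlier_id[rv$later_id == 3 & rv$is_revisit], 2L)
})

test_that("bearing variance matches closed-form circular statistics", {
  # constant bearing: due north hops
  cent <- cbind(lon = rep(60, 4), lat = c(60, 61, 62, 63))
  expect_equal(bearing_variance(cent), 0, tolerance = 1e-9)
  # out-and-back: two bearings 180 degrees apart
  cent <- cbind(lon = c(60, 60, 60), lat = c(60, 62, 60))
  expect_equal(bearing_variance(cent), 1, tolerance = 1e-9)
  # bearings 0 and 90 degrees: 1 - sqrt(2)/2 (on the equator, where
  # great-circle bearings match plane bearings)
  cent <- cbind(lon = c(0, 0, 1), lat = c(0, 1, 1))
  expect_equal(bearing_variance(cent), 1 - sqrt(2) / 2, tolerance = 1e-2)
  # undefined below two sites
  expect_true(is.na(bearing_variance(cbind(lon = 60, lat = 60))))
})

test_that("bearing variance is invariant under rotation about the pole", {
  set.seed(61)
  cent <- cbind(lon = runif(6, 40, 50), lat = runif(6, 60, 65))
  bv <- bearing_variance(cent)
  rot <- cent; rot[, "lon"] <- rot[, "lon"] + 25
  expect_equal(bearing_variance(rot), bv, tolerance = 1e-6)
})

test_that("a square itinerary yields the stated distances and rates", {
  # 4 sites on a 300-km square at mid latitude
  start <- c(60, 64)
  p2 <- geosphere::destPoint(start, 90, 300e3, a = 6371000, f = 0)
  p3 <- geosphere::destPoint(p2, 0, 300e3, a = 6371000, f = 0)
  p4 <- geosphere::destPoint(p3, 270, 300e3, a = 6371000, f = 0)
  cent <- rbind(start, p2[1, ], p3[1, ], p4[1, ])
  areas <- make_areas(cent, tenures = c(5, 1, 1, 1), gap_days = 1.5)
  # a regular track tracing the centroids over 14 days
  t0 <- areas[[1]]$arrival
  reg_t <- seq(0, 14, by = 900 / 86400)
  seg <- floor(pmin(reg_t / 3.5, 3))
  frac <- (reg_t - seg * 3.5) / 3.5
  path <- cent[seg + 1, , drop = FALSE] +
    (cent[pmin(seg + 2, 4), , drop = FALSE] - cent[seg + 1, , drop = FALSE]) * frac
  xy <- laea_project(path[, 1], path[, 2])
  reg <- data.frame(id = "sq", timestamp = t0 + reg_t * 86400,
                    x = xy[, "x"], y = xy[, "y"],
                    lon = path[, 1], lat = path[, 2], var_x = 0, var_y = 0)
  s <- summarize_individual(areas, extract_transits(reg, areas), reg)
  expect_equal(s$n_sites, 4)
  expect_equal(s$sites_per_week, 2, tolerance = 1e-6)
  between <- c(dist_km(cent[1, ], cent[2, ]), dist_km(cent[2, ], cent[3, ]),
               dist_km(cent[3, ], cent[4, ]))
  expect_true(all(abs(between - 300) / 300 < 0.02))
  expect_equal(s$sum_between_site_km, sum(between), tolerance = 0.01)
  # total path length is at least the straight first-to-last distance
  expect_gte(s$total_distance_km,
             dist_km(c(reg$lon[1], reg$lat[1]),
                     c(reg$lon[nrow(reg)], reg$lat[nrow(reg)])) - 1e-6)
  # longest tenure is the first site; the after-period holds the three
  # remaining corners, whose two successive bearings differ by 90 degrees
  expect_equal(s$longest_tenure_area_id, 1)
  expect_true(is.na(s$bearing_variance_before)) # no site before
  expect_true(is.na(s$mean_tenure_before))
  expect_equal(s$bearing_variance_after, 1 - sqrt(2) / 2, tolerance = 0.05)
  expect_equal(s$mean_tenure_after, 1)
})

test_that("single-site individuals produce degenerate but valid summaries", {
  areas <- make_areas(cbind(lon = 60, lat = 64), tenures = 2)
  t0 <- areas[[1]]$arrival
  xy <- laea_project(60, 64)
  reg <- data.frame(id = "one", timestamp = t0 + seq(0, 2 * 86400, 900),
                    x = unname(xy[1, "x"]), y = unname(xy[1, "y"]),
                    lon = 60, lat = 64, var_x = 0, var_y = 0)
  s <- summarize_individual(areas, extract_transits(reg, areas), reg)
  expect_equal(s$n_sites, 1)
  expect_equal(s$sum_between_site_km, 0)
  expect_equal(s$pct_time_travelling, 0)
  expect_true(is.na(s$bearing_variance))
})

test_that("zero areas give an empty summary row", {
  reg <- data.frame(id = "none",
                    timestamp = as.POSIXct("2022-05-01", tz = "UTC") +
                      seq(0, 86400, 900),
                    x = 0, y = 0, lon = 45, lat = 80, var_x = 0, var_y = 0)
  s <- summarize_individual(structure(list(), class = "residency_areas"),
                            list(), reg)
  expect_equal(s$n_sites, 0)
  expect_true(is.na(s$mean_tenure_days))
})

test_that("translating hulls apart removes all revisits", {
  set.seed(62)
  cent <- cbind(lon = 60 + cumsum(runif(5, 1, 2)), lat = rep(64, 5))
  areas <- make_areas(cent, hull_r = 2000)
  rv <- detect_revisits(areas)
  expect_equal(sum(rv$is_revisit), 0)
})

test_that("the paired contrast is exact for identical periods", {
  s <- data.frame(bearing_variance_before = c(0.2, 0.4, 0.3),
                  bearing_variance_after = c(0.2, 0.4, 0.3))
  ct <- before_after_contrast(s, "bearing_variance")
  expect_equal(ct$mean_difference, 0)
  expect_equal(ct$p_value, 1)
})

test_that("permutation p matches exhaustive enumeration at n = 5", {
  set.seed(63)
  b <- runif(5); a <- b + rnorm(5, 0.3, 0.2)
  s <- data.frame(mean_tenure_before = b, mean_tenure_after = a)
  ct <- before_after_contrast(s, "mean_tenure")
  expect_true(ct$exhaustive)
  # independent enumeration of all 32 sign patterns
  d <- a - b
  stats <- vapply(0:31, function(m) {
    sg <- ifelse(bitwAnd(m, 2^(0:4)) > 0, 1, -1)
    abs(mean(sg * d))
  }, numeric(1))
  p_manual <- mean(stats >= abs(mean(d)) - 1e-12)
  expect_equal(ct$p_value, p_manual)
})

test_that("a constructed goal-oriented cohort is detected at n = 20", {
  set.seed(64)
  b <- runif(20, 0.05, 0.15)  # direct approach: low bearing variance
  a <- runif(20, 0.45, 0.75)  # dispersed afterwards
  s <- data.frame(bearing_variance_before = b, bearing_variance_after = a)
  ct <- before_after_contrast(s, "bearing_variance", seed = 64)
  expect_lt(ct$p_value, 0.05)
})

test_that("individuals lacking a period are excluded with a message", {
  s <- data.frame(mean_tenure_before = c(1, 2, NA, 3),
                  mean_tenure_after = c(2, 3, 4, 5))
  expect_message(ct <- before_after_contrast(s, "mean_tenure"), "excluded")
  expect_equal(ct$n, 3)
})
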