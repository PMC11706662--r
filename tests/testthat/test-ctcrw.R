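sim_model_track <- function(n, beta, sigma, dt_d = 0.05, tau_m = 500,
                            seed = 1, irregular = FALSE) {
  set.seed(seed)
  tt <- if (irregular) cumsum(runif(n, 0.2, 1.8) * dt_d) else (0:(n - 1)) * dt_d
  path <- simulate_ctcrw_path(tt, beta, sigma, start = c(0, 0), seed = seed)
  set.seed(seed + 1)
  make_model_obs(tt, path, tau_m)
}

make_model_obs <- function(tt, path, tau_m) {
  t0 <- as.POSIXct("2022-05-01 00:00:00", tz = "UTC")
  data.frame(id = "m", timestamp = t0 + tt * 86400,
             lon = NA_real_, lat = NA_real_, lc = "3",
             error_radius_m = tau_m,
             x = path[, 1] + rnorm(length(tt), 0, tau_m),
             y = path[, 2] + rnorm(length(tt), 0, tau_m),
             true_x = path[, 1], true_y = path[, 2])
}

test_that("log-likelihood peaks near the generating parameters", {
  tr <- sim_model_track(500, beta = 2, sigma = 5e4, seed = 1)
  p0 <- list(beta = 2, sigma = 5e4)
  ll0 <- ctcrw_loglik(tr, p0)
  expect_gt(ll0, ctcrw_loglik(tr, list(beta = 4, sigma = 5e4)))
  expect_gt(ll0, ctcrw_loglik(tr, list(beta = 2, sigma = 1e5)))
})

test_that("state covariance approaches the stationary velocity variance", {
  beta <- 5; sigma <- 2e4
  sys <- nomadtrack:::ctcrw_system(beta, sigma, 50)
  expect_equal(sys$Q[2, 2], sigma^2 / (2 * beta), tolerance = 1e-10)
})

test_that("Kalman log-likelihood equals the dense joint-Gaussian density", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    tt <- sort(runif(n, 0, 5))
    tt <- tt - tt[1]
    beta <- runif(1, 0.5, 8)
    sigma <- runif(1, 1e3, 1e5)
    tau <- runif(n, 100, 3000)
    zx <- cumsum(rnorm(n, 0, 2e3))
    zy <- cumsum(rnorm(n, 0, 2e3))
    flt <- nomadtrack:::ctcrw_filter(tt, cbind(zx, zy), tau^2, beta, sigma,
                                     init_pos_var = 1e10)
    dense <- dense_ctcrw_loglik(tt, zx, zy, tau^2, beta, sigma,
                                pos_var = 1e10)
    expect_equal(flt$loglik, dense, tolerance = 1e-6)
  }
})

test_that("parameters are recovered from model-simulated data", {
  errs <- sapply(1:5, function(s) {
    tr <- sim_model_track(300, beta = 2, sigma = 5e4, seed = 100 + s)
    fit <- fit_ctcrw(tr)
    c(abs(fit$beta - 2) / 2, abs(fit$sigma - 5e4) / 5e4)
  })
  expect_lt(median(errs[1, ]), 0.4)
  expect_lt(median(errs[2, ]), 0.4)
})

test_that("rescaling time rescales beta accordingly", {
  tr <- sim_model_track(400, beta = 3, sigma = 4e4, seed = 7)
  fit1 <- fit_ctcrw(tr)
  # stretch time 24x: the same trajectory observed in a slower clock
  tr24 <- tr
  t0 <- tr$timestamp[1]
  tr24$timestamp <- t0 + as.numeric(tr$timestamp - t0, units = "secs") * 24
  fit24 <- fit_ctcrw(tr24)
  expect_equal(fit24$beta, fit1$beta / 24, tolerance = 0.05 * fit1$beta)
})

test_that("a nearly stationary animal shrinks to a tight path", {
  set.seed(51)
  tt <- seq(0, 12, by = 1 / 12)
  tr <- make_model_obs(tt, matrix(0, length(tt), 2), tau_m = 1500)
  fit <- fit_ctcrw(tr)
  reg <- predict_regular(tr, fit)
  expect_lt(stats::var(reg$x), stats::var(tr$x) / 4)
})

test_that("smoothing beats the raw fixes in RMSE to truth", {
  tr <- sim_model_track(500, beta = 2, sigma = 5e4, seed = 2)
  fit <- fit_ctcrw(tr)
  reg <- predict_regular(tr, fit, interval_s = 3600)
  # compare at fix times via the merged grid: interpolate smoothed path
  sx <- approx(as.numeric(reg$timestamp), reg$x,
               xout = as.numeric(tr$timestamp), rule = 2)$y
  sy <- approx(as.numeric(reg$timestamp), reg$y,
               xout = as.numeric(tr$timestamp), rule = 2)$y
  rmse_raw <- sqrt(mean((tr$x - tr$true_x)^2 + (tr$y - tr$true_y)^2))
  rmse_sm <- sqrt(mean((sx - tr$true_x)^2 + (sy - tr$true_y)^2))
  expect_lt(rmse_sm, rmse_raw)
})

test_that("noise-free constant-velocity data predicts on the line", {
  tt <- seq(0, 2, by = 1 / 24)
  path <- cbind(1e4 * tt * 24, 5e3 * tt * 24) # straight line
  tr <- make_model_obs(tt, path, tau_m = 0)
  tr$error_radius_m <- 1e-3
  # beta ~ 0: the integrated random walk limit, whose smoothed mean
  # through noiseless collinear fixes is the straight line itself
  reg <- predict_regular(tr, list(beta = 0.01, sigma = 1e5))
  gt <- as.numeric(difftime(reg$timestamp, tr$timestamp[1], units = "days"))
  expect_lt(max(abs(reg$x - 1e4 * gt * 24)), 1)
  expect_lt(max(abs(reg$y - 5e3 * gt * 24)), 1)
})

test_that("the prediction grid is spaced exactly 15 minutes", {
  tr <- sim_model_track(50, beta = 2, sigma = 5e4, seed = 3, dt_d = 0.04)
  reg <- predict_regular(tr, list(beta = 2, sigma = 5e4))
  expect_true(all(diff(as.numeric(reg$timestamp)) == 900))
})

test_that("smoother variance never exceeds filter variance", {
  tr <- sim_model_track(200, beta = 2, sigma = 5e4, seed = 4,
                        irregular = TRUE)
  sm <- predict_regular(tr, list(beta = 2, sigma = 5e4))
  fl <- predict_regular(tr, list(beta = 2, sigma = 5e4), smooth = FALSE)
  expect_true(all(sm$var_x <= fl$var_x + 1e-6))
})

test_that("predictions are equivariant under translation and rotation", {
  tr <- sim_model_track(150, beta = 2, sigma = 5e4, seed = 5)
  reg <- predict_regular(tr, list(beta = 2, sigma = 5e4))
  # translation
  tr2 <- tr; tr2$x <- tr$x + 1e5; tr2$y <- tr$y - 2e5
  reg2 <- predict_regular(tr2, list(beta = 2, sigma = 5e4))
  expect_equal(reg2$x, reg$x + 1e5, tolerance = 1e-4)
  expect_equal(reg2$y, reg$y - 2e5, tolerance = 1e-4)
  # rotation by 90 degrees: (x, y) -> (-y, x)
  tr3 <- tr; tr3$x <- -tr$y; tr3$y <- tr$x
  reg3 <- predict_regular(tr3, list(beta = 2, sigma = 5e4))
  expect_equal(reg3$x, -reg$y, tolerance = 1e-4)
  expect_equal(reg3$y, reg$x, tolerance = 1e-4)
})

test_that("transit extraction respects closed hull boundaries", {
  # regular track marching east; one hull covering the middle third
  n <- 30
  reg <- data.frame(id = "t", timestamp = as.POSIXct("2022-05-01",
                                                     tz = "UTC") + (1:n) * 900,
                    x = (1:n) * 1000, y = 0)
  ll <- laea_unproject(reg$x, reg$y)
  reg$lon <- ll[, "lon"]; reg$lat <- ll[, "lat"]
  reg$var_x <- 0; reg$var_y <- 0
  hull <- cbind(x = c(10000, 20000, 20000, 10000),
                y = c(-500, -500, 500, 500))
  area <- list(area_id = 1L, hull = hull)
  segs <- extract_transits(reg, list(area))
  expect_length(segs, 2)
  # the point exactly on the boundary (x = 10000 or 20000) is inside
  inside_idx <- setdiff(1:n, unlist(lapply(segs, function(s)
    which(reg$timestamp %in% s$points$timestamp))))
  expect_true(10 %in% inside_idx && 20 %in% inside_idx)
  # all inside one hull: no segments
  big <- list(area_id = 2L,
              hull = cbind(x = c(0, 4e4, 4e4, 0), y = c(-1, -1, 1, 1) * 1e3))
  expect_length(extract_transits(reg, list(big)), 0)
  # no areas: a single segment spanning the whole track
  whole <- extract_transits(reg, list())
  expect_length(whole, 1)
  expect_equal(nrow(whole[[1]]$points), n)
})

test_that("two-site itineraries yield one transit of the right duration", {
  cfg <- sim_config(n_sites = 2, tenure_median_days = 5, tenure_sdlog = 0.1)
  it <- simulate_itinerary(cfg, seed = 12)
  smp <- sampling_config(fix_interval_h = 0.25, duty_on_h = 24,
                         duty_off_h = 0, jitter_frac = 0)
  tr <- simulate_argos_observations(it, zero_noise_model(), smp, seed = 12)
  tr <- project_track(tr)
  areas <- find_residency_areas(tr, cluster_params())
  expect_equal(length(areas), 2)
  fit <- fit_ctcrw(tr, zero_noise_model())
  reg <- predict_regular(tr, fit, zero_noise_model())
  segs <- extract_transits(reg, areas)
  segs <- segs[vapply(segs, `[[`, numeric(1), "duration_days") > 0.05]
  expect_length(segs, 1)
  true_dur <- as.numeric(difftime(it$transits$arrival[1],
                                  it$transits$departure[1], units = "days"))
  expect_lt(abs(segs[[1]]$duration_days - true_dur), 2 * 900 / 86400 + 0.01)
})
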