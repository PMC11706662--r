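# Continuous-time correlated random walk (CTCRW): per axis the velocity
# is an Ornstein-Uhlenbeck process with autocorrelation rate beta (1/day)
# and diffusion scale sigma (m / day^1.5); position integrates velocity.
# Both axes share (beta, sigma). Observations are the projected fix
# coordinates plus zero-mean Gaussian measurement error whose sd is the
# Argos-class sd (or the per-fix error radius where reported).

# state transition and process covariance over a gap of dt days
ctcrw_system <- function(beta, sigma, dt) {
  if (dt <= 0) {
    return(list(T = diag(2), Q = matrix(0, 2, 2)))
  }
  e1 <- exp(-beta * dt)
  e2 <- exp(-2 * beta * dt)
  Tm <- matrix(c(1, 0, (1 - e1) / beta, e1), 2, 2)
  if (beta * dt < 1e-4) {
    # series expansion: the closed forms cancel catastrophically here
    qpp <- sigma^2 * dt^3 / 3
    qvv <- sigma^2 * dt * (1 - beta * dt)
    qpv <- sigma^2 * dt^2 / 2
  } else {
    qpp <- (sigma^2 / beta^2) *
      (dt - (2 / beta) * (1 - e1) + (1 / (2 * beta)) * (1 - e2))
    qvv <- (sigma^2 / (2 * beta)) * (1 - e2)
    qpv <- (sigma^2 / (2 * beta^2)) * (1 - e1)^2
  }
  list(T = Tm, Q = matrix(c(max(qpp, 0), qpv, qpv, max(qvv, 0)), 2, 2))
}

# initial state: diffuse position (sd 1e7 m), stationary velocity
ctcrw_init_cov <- function(beta, sigma, pos_var = 1e14) {
  matrix(c(pos_var, 0, 0, sigma^2 / (2 * beta)), 2, 2)
}

# shared Kalman forward pass over a merged time grid, written in scalar
# form (symmetric 2x2 covariance as p11/p12/p22; the x and y axes share
# every covariance because they share parameters and measurement noise).
# times: numeric days, strictly increasing; obs: n x 2 matrix with NA
# rows at prediction-only times; tau2: measurement variance per row.
# The Joseph-form update keeps the covariance positive under the diffuse
# position prior.
ctcrw_filter <- function(times, obs, tau2, beta, sigma,
                         init_pos_var = 1e14) {
  n <- length(times)
  mp1x <- mp1y <- mp2x <- mp2y <- numeric(n)  # predicted state means
  pp11 <- pp12 <- pp22 <- numeric(n)          # predicted covariances
  mf1x <- mf1y <- mf2x <- mf2y <- numeric(n)  # filtered
  pf11 <- pf12 <- pf22 <- numeric(n)
  Ta <- rep(0, n); Te <- rep(1, n)            # transition (a, e) per step
  ll <- 0
  m1x <- m1y <- m2x <- m2y <- 0
  P0 <- ctcrw_init_cov(beta, sigma, init_pos_var)
  p11 <- P0[1, 1]; p12 <- 0; p22 <- P0[2, 2]
  dts <- c(0, diff(times))
  for (k in seq_len(n)) {
    dt <- dts[k]
    if (k > 1 && dt > 0) {
      sys <- ctcrw_system(beta, sigma, dt)
      a <- sys$T[1, 2]; e <- sys$T[2, 2]
      Ta[k] <- a; Te[k] <- e
      m1x <- m1x + a * m2x; m1y <- m1y + a * m2y
      m2x <- e * m2x; m2y <- e * m2y
      q <- sys$Q
      np11 <- p11 + 2 * a * p12 + a * a * p22 + q[1, 1]
      np12 <- e * (p12 + a * p22) + q[1, 2]
      np22 <- e * e * p22 + q[2, 2]
      p11 <- np11; p12 <- np12; p22 <- np22
    }
    mp1x[k] <- m1x; mp1y[k] <- m1y; mp2x[k] <- m2x; mp2y[k] <- m2y
    pp11[k] <- p11; pp12[k] <- p12; pp22[k] <- p22
    if (!is.na(obs[k, 1])) {
      S <- p11 + tau2[k]
      ex <- obs[k, 1] - m1x; ey <- obs[k, 2] - m1y
      K1 <- p11 / S; K2 <- p12 / S
      m1x <- m1x + K1 * ex; m1y <- m1y + K1 * ey
      m2x <- m2x + K2 * ex; m2y <- m2y + K2 * ey
      A <- 1 - K1
      t2 <- tau2[k]
      np11 <- A * A * p11 + t2 * K1 * K1
      np12 <- A * (p12 - K2 * p11) + t2 * K1 * K2
      np22 <- p22 - 2 * K2 * p12 + K2 * K2 * p11 + t2 * K2 * K2
      p11 <- np11; p12 <- np12; p22 <- np22
      ll <- ll - 0.5 * (2 * log(2 * pi * S) + (ex * ex + ey * ey) / S)
    }
    mf1x[k] <- m1x; mf1y[k] <- m1y; mf2x[k] <- m2x; mf2y[k] <- m2y
    pf11[k] <- p11; pf12[k] <- p12; pf22[k] <- p22
  }
  list(loglik = unname(ll),
       m_pred = list(p1x = mp1x, p1y = mp1y, p2x = mp2x, p2y = mp2y),
       P_pred = list(p11 = pp11, p12 = pp12, p22 = pp22),
       m_filt = list(p1x = mf1x, p1y = mf1y, p2x = mf2x, p2y = mf2y),
       P_filt = list(p11 = pf11, p12 = pf12, p22 = pf22),
       Ta = Ta, Te = Te, n = n)
}

# Rauch-Tung-Striebel backward smoother on a filter result
ctcrw_smooth <- function(flt) {
  n <- flt$n
  s1x <- flt$m_filt$p1x; s1y <- flt$m_filt$p1y
  s2x <- flt$m_filt$p2x; s2y <- flt$m_filt$p2y
  s11 <- flt$P_filt$p11; s12 <- flt$P_filt$p12; s22 <- flt$P_filt$p22
  if (n > 1) {
    for (k in (n - 1):1) {
      a <- flt$Ta[k + 1]; e <- flt$Te[k + 1]
      # P_f T' with T = [[1, a], [0, e]]
      f11 <- flt$P_filt$p11[k]; f12 <- flt$P_filt$p12[k]
      f22 <- flt$P_filt$p22[k]
      b11 <- f11 + a * f12; b12 <- e * f12
      b21 <- f12 + a * f22; b22 <- e * f22
      Pp <- matrix(c(flt$P_pred$p11[k + 1], flt$P_pred$p12[k + 1],
                     flt$P_pred$p12[k + 1], flt$P_pred$p22[k + 1]), 2, 2)
      Pi <- psd_inv(Pp)
      c11 <- b11 * Pi[1, 1] + b12 * Pi[2, 1]
      c12 <- b11 * Pi[1, 2] + b12 * Pi[2, 2]
      c21 <- b21 * Pi[1, 1] + b22 * Pi[2, 1]
      c22 <- b21 * Pi[1, 2] + b22 * Pi[2, 2]
      d1x <- s1x[k + 1] - flt$m_pred$p1x[k + 1]
      d2x <- s2x[k + 1] - flt$m_pred$p2x[k + 1]
      d1y <- s1y[k + 1] - flt$m_pred$p1y[k + 1]
      d2y <- s2y[k + 1] - flt$m_pred$p2y[k + 1]
      s1x[k] <- flt$m_filt$p1x[k] + c11 * d1x + c12 * d2x
      s2x[k] <- flt$m_filt$p2x[k] + c21 * d1x + c22 * d2x
      s1y[k] <- flt$m_filt$p1y[k] + c11 * d1y + c12 * d2y
      s2y[k] <- flt$m_filt$p2y[k] + c21 * d1y + c22 * d2y
      # P_s[k] = P_f + C (P_s[k+1] - P_pred[k+1]) C'
      e11 <- s11[k + 1] - Pp[1, 1]; e12 <- s12[k + 1] - Pp[1, 2]
      e22 <- s22[k + 1] - Pp[2, 2]
      g11 <- c11 * e11 + c12 * e12; g12 <- c11 * e12 + c12 * e22
      g21 <- c21 * e11 + c22 * e12; g22 <- c21 * e12 + c22 * e22
      s11[k] <- f11 + g11 * c11 + g12 * c12
      s12[k] <- f12 + g11 * c21 + g12 * c22
      s22[k] <- f22 + g21 * c21 + g22 * c22
    }
  }
  list(m = list(p1x = s1x, p1y = s1y, p2x = s2x, p2y = s2y),
       P = list(p11 = s11, p12 = s12, p22 = s22))
}

track_time_days <- function(track) {
  as.numeric(track$timestamp) / 86400
}

#' CTCRW log-likelihood of a projected track
#'
#' Exact Gaussian log-likelihood via the Kalman filter, both axes
#' sharing the movement parameters. Measurement sd per fix comes from
#' [measurement_sd()].
#'
#' @param track projected track data.frame (x, y, timestamp, lc,
#'   error_radius_m).
#' @param params list with positive `beta` (1/day) and `sigma`
#'   (m/day^1.5).
#' @param error_model an [argos_error_model()].
#' @param init_pos_var prior position variance (m^2) of the diffuse
#'   initial state.
#' @return log-likelihood (numeric scalar).
#' @export
ctcrw_loglik <- function(track, params, error_model = default_error_model(),
                         init_pos_var = 1e14) {
  if (nrow(track) < 4) stop("need at least 4 fixes")
  if (!is.finite(params$beta) || !is.finite(params$sigma) ||
      params$beta <= 0 || params$sigma <= 0)
    stop("beta and sigma must be positive")
  tt <- track_time_days(track)
  if (any(diff(tt) <= 0)) stop("duplicate or non-increasing timestamps")
  tau <- measurement_sd(track$lc, track$error_radius_m, error_model)
  flt <- ctcrw_filter(tt - tt[1], cbind(track$x, track$y), tau^2,
                      params$beta, params$sigma, init_pos_var)
  flt$loglik
}

#' Fit the CTCRW to one individual's track
#'
#' Maximises the Kalman log-likelihood over (log beta, log sigma) with
#' BFGS from a deterministic initialisation (beta0 = 1/mean gap; sigma0
#' from the empirical step-velocity variance), with two fixed fallback
#' starts. Deterministic given the input.
#'
#' @param track projected track (>= 10 fixes spanning > 1 day).
#' @param error_model an [argos_error_model()].
#' @param init optional list(beta, sigma) overriding the default start.
#' @return `ctcrw_params`: list(beta, sigma, loglik, converged).
#' @export
fit_ctcrw <- function(track, error_model = default_error_model(),
                      init = NULL) {
  if (nrow(track) < 10) stop("need at least 10 fixes")
  tt <- track_time_days(track)
  if (tt[length(tt)] - tt[1] <= 1) stop("track must span more than 1 day")
  if (is.null(init)) {
    gap <- mean(diff(tt))
    beta0 <- 1 / gap
    v_emp <- sqrt(diff(track$x)^2 + diff(track$y)^2) / diff(tt)
    sigma0 <- max(stats::sd(v_emp), 1) * sqrt(2 * beta0)
    init <- list(beta = beta0, sigma = sigma0)
  }
  tau <- measurement_sd(track$lc, track$error_radius_m, error_model)
  obs <- cbind(track$x, track$y)
  negll <- function(theta) {
    b <- exp(theta[1]); s <- exp(theta[2])
    if (!is.finite(b) || !is.finite(s)) return(1e12)
    ll <- tryCatch(
      suppressWarnings(ctcrw_filter(tt - tt[1], obs, tau^2, b, s)$loglik),
      error = function(e) -1e12)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  starts <- list(c(log(init$beta), log(init$sigma)),
                 c(log(init$beta) + log(5), log(init$sigma) - log(5)),
                 c(log(init$beta) - log(5), log(init$sigma) + log(5)))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(stats::optim(s0, negll, method = "BFGS",
                                 control = list(maxit = 200)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best))
    return(structure(list(beta = init$beta, sigma = init$sigma,
                          loglik = NA_real_, converged = FALSE),
                     class = "ctcrw_params"))
  structure(list(beta = exp(best$par[1]), sigma = exp(best$par[2]),
                 loglik = -best$value,
                 converged = best$convergence == 0),
            class = "ctcrw_params")
}

#' Predict the track on a regular grid (RTS smoother)
#'
#' Runs the Kalman filter over the union of fix times and a regular grid
#' anchored at the first fix, then the Rauch-Tung-Striebel smoother, and
#' returns the smoothed positions and per-axis position variances at the
#' grid times. The default 15-min grid matches the study's prediction
#' interval.
#'
#' @param track projected track.
#' @param params fitted `ctcrw_params` (or list with beta, sigma).
#' @param error_model an [argos_error_model()].
#' @param interval_s grid spacing in seconds (default 900 = 15 min).
#' @param smooth use the RTS smoother (default); FALSE returns filtered
#'   states instead.
#' @return `regular_track` data.frame: id, timestamp, x, y, lon, lat,
#'   var_x, var_y.
#' @export
predict_regular <- function(track, params,
                            error_model = default_error_model(),
                            interval_s = 900, smooth = TRUE) {
  stopifnot(nrow(track) >= 2)
  tt <- track_time_days(track)
  t0 <- tt[1]
  grid_d <- seq(0, tt[length(tt)] - t0, by = interval_s / 86400)
  fix_d <- tt - t0
  all_d <- sort(unique(round(c(grid_d, fix_d) * 86400))) / 86400
  is_fix <- !is.na(match(round(all_d * 86400), round(fix_d * 86400)))
  fix_of <- match(round(all_d * 86400), round(fix_d * 86400))
  obs <- matrix(NA_real_, length(all_d), 2)
  obs[is_fix, ] <- cbind(track$x, track$y)[fix_of[is_fix], ]
  tau <- measurement_sd(track$lc, track$error_radius_m, error_model)
  tau2 <- rep(0, length(all_d))
  tau2[is_fix] <- tau[fix_of[is_fix]]^2
  flt <- ctcrw_filter(all_d, obs, tau2, params$beta, params$sigma)
  if (smooth) {
    sm <- ctcrw_smooth(flt)
    mm <- sm$m; PP <- sm$P
  } else {
    mm <- flt$m_filt; PP <- flt$P_filt
  }
  gi <- match(round(grid_d * 86400), round(all_d * 86400))
  x <- mm$p1x[gi]
  y <- mm$p1y[gi]
  v <- PP$p11[gi]
  ll <- laea_unproject(x, y)
  out <- data.frame(
    id = track$id[1],
    timestamp = as.POSIXct((t0 + grid_d) * 86400, tz = "UTC",
                           origin = "1970-01-01"),
    x = x, y = y, lon = ll[, "lon"], lat = ll[, "lat"],
    var_x = pmax(v, 0), var_y = pmax(v, 0))
  class(out) <- c("regular_track", "data.frame")
  out
}

#' Simulate positions exactly from the CTCRW (test oracle helper)
#'
#' Draws states at the given times from the model's exact discrete-time
#' transition, starting from position `start` with stationary velocity.
#'
#' @param times numeric vector of times in days, increasing.
#' @param beta,sigma CTCRW parameters.
#' @param start numeric length-2 start position (metres).
#' @param seed integer seed.
#' @return matrix with columns x, y of true positions.
#' @export
simulate_ctcrw_path <- function(times, beta, sigma, start = c(0, 0), seed) {
  set.seed(as.integer(seed))
  n <- length(times)
  out <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
  vstat <- sqrt(sigma^2 / (2 * beta))
  st <- rbind(start, stats::rnorm(2, 0, vstat)) # 2x2: state x axis
  out[1, ] <- st[1, ]
  for (k in 2:n) {
    sys <- ctcrw_system(beta, sigma, times[k] - times[k - 1])
    L <- chol_psd(sys$Q)
    st <- sys$T %*% st + L %*% matrix(stats::rnorm(4), 2, 2)
    out[k, ] <- st[1, ]
  }
  out
}

# pseudo-inverse of a symmetric PSD 2x2 (near-singular process noise)
psd_inv <- function(P, rtol = 1e-12) {
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE)
  tol <- rtol * max(ev$values, 0)
  inv <- ifelse(ev$values > tol, 1 / ev$values, 0)
  ev$vectors %*% diag(inv, nrow = 2) %*% t(ev$vectors)
}

# lower-triangular factor tolerant of semi-definite Q (dt -> 0)
chol_psd <- function(Q) {
  ev <- eigen(Q, symmetric = TRUE)
  val <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(val), nrow = length(val))
}

#' Extract transit segments from a regular track
#'
#' Grid points inside any residency hull (closed polygons: boundary
#' points count as inside) are discarded; maximal runs of retained
#' points become transit segments with a duration and a great-circle
#' path length.
#'
#' @param regular a `regular_track` from [predict_regular()].
#' @param areas a `residency_areas` object.
#' @return list of segments: each a list(points, duration_days, path_km).
#' @export
extract_transits <- function(regular, areas) {
  n <- nrow(regular)
  if (n == 0) return(list())
  inside <- rep(FALSE, n)
  xy <- cbind(regular$x, regular$y)
  for (a in areas) {
    inside <- inside | point_in_convex(xy, a$hull, tol = 1e-6)
  }
  runs <- rle(!inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    idx <- starts[r]:ends[r]
    pts <- regular[idx, , drop = FALSE]
    dur <- as.numeric(difftime(pts$timestamp[nrow(pts)], pts$timestamp[1],
                               units = "days"))
    path <- 0
    if (nrow(pts) > 1) {
      p <- cbind(pts$lon, pts$lat)
      path <- sum(geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                           p[-1, , drop = FALSE],
                                           r = EARTH_RADIUS_M)) / 1000
    }
    segs[[length(segs) + 1L]] <- list(points = pts, duration_days = dur,
                                      path_km = path)
  }
  segs
}
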