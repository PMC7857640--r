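#' Label the sensory-switch series from synchronization error
#'
#' Decides, frame by frame, whether the fish is following the local
#' circulation. Both inputs are normalised to `[-1, 1]` by their maximum
#' absolute value; the strength-difference (turn) signal is smoothed with
#' a centered moving average; the synchronization error is
#' `e = sqrt((omega_hat - s)^2 + (circ_hat - s)^2)` with `s` the mean of
#' the two signals. `K = 1` at every instant covered by a window of at
#' least `window_s` seconds throughout which `e` stays below `threshold`
#' (the continuous-window rule filters out chance alignment).
#'
#' @param omega_a Strength-difference series `gamma_l - gamma_r`, cm^2/s.
#' @param circ Local-circulation series, cm^2/s (same length).
#' @param dt Sampling period, s.
#' @param window_s Minimum synchronised window, s.
#' @param threshold Synchronization-error threshold on the normalised
#'   scale.
#' @param smooth_n Moving-average length, samples (0.5 s at 30 Hz).
#' @return Integer 0/1 series, same length as the inputs.
#' @export
label_k_series <- function(omega_a, circ, dt = 1 / 30, window_s = 2,
                           threshold = 0.35, smooth_n = 15) {
  if (length(omega_a) != length(circ))
    stop("series must be aligned and of equal length", call. = FALSE)
  m1 <- max(abs(omega_a)); m2 <- max(abs(circ))
  if (m1 == 0 || m2 == 0)
    stop("all-zero series: normalization undefined", call. = FALSE)
  w_hat <- omega_a / m1
  c_hat <- circ / m2
  sm <- as.numeric(stats::filter(w_hat, rep(1 / smooth_n, smooth_n),
                                 sides = 2))
  w_hat <- ifelse(is.na(sm), w_hat, sm)
  s <- (w_hat + c_hat) / 2
  e <- sqrt((w_hat - s)^2 + (c_hat - s)^2)
  below <- e < threshold
  w_len <- ceiling(window_s / dt)
  k <- integer(length(below))
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in seq_along(runs$values))
    if (runs$values[i] && runs$lengths[i] >= w_len)
      k[starts[i]:ends[i]] <- 1L
  k
}

#' Maximum-likelihood switching rates of a two-state Markov chain
#'
#' Counts transitions of the labelled switch series and normalises each
#' count by the total time spent in the departing state:
#' `lambda1 = n(0 -> 1) / time_in_0`, `lambda2 = n(1 -> 0) / time_in_1`
#' (the continuous-time Markov chain MLE). A state never visited yields
#' `NA` for its rate (undefined, not zero).
#'
#' @param k_series Integer 0/1 series.
#' @param dt Sampling period, s.
#' @return Named numeric vector `c(lambda1 =, lambda2 =)`, 1/s.
#' @export
estimate_switch_rates <- function(k_series, dt = 1 / 30) {
  n <- length(k_series)
  if (n < 2) stop("series length must be >= 2", call. = FALSE)
  from <- k_series[-n]; to <- k_series[-1L]
  t0 <- sum(from == 0L) * dt
  t1 <- sum(from == 1L) * dt
  c(lambda1 = if (t0 > 0) sum(from == 0L & to == 1L) / t0 else NA_real_,
    lambda2 = if (t1 > 0) sum(from == 1L & to == 0L) / t1 else NA_real_)
}

# Standardised Euler-Maruyama residuals of the coupled CIR chain.
# X = state at k, Y = state at k+1, Z = opposite vortex at k, hydro =
# K * Lc at k. `hs` is +1 for the left vortex, -1 for the right.
em_residual <- function(X, Y, Z, hydro, hs, alpha, beta, kappa, k_r, dt, k0) {
  (Y + X * (alpha * dt + kappa * dt - 1) - alpha * beta * dt -
     kappa * dt * Z - hs * k_r * hydro * dt) / (k0 * sqrt(X))
}

#' Constrained maximum-likelihood estimation of the SDE parameters
#'
#' Estimates `Theta = (alpha, beta, sigma/K0, kappa, k_r)` from paired
#' vortex-strength series by maximising the Gaussian likelihood of the
#' standardised Euler--Maruyama residuals (residual of the discrete step
#' divided by `K0 sqrt(Gamma)`, each with variance `(sigma/K0)^2 dt`),
#' subject to the Feller constraint `sigma^2 < 2 alpha beta`. Only frames
#' where `away_mask` is `TRUE` at both ends of the step contribute (the
#' visual wall term is neglected, valid away from walls). The constraint
#' is enforced by reparameterisation, `sigma^2 = 2 alpha beta *
#' plogis(s)`, so every iterate is strictly feasible; optimisation is a
#' quasi-Newton search from five deterministic multistarts around a
#' weighted-least-squares initial value (the Euler drift is linear in the
#' transformed parameters).
#'
#' @param gamma_l,gamma_r Vortex-strength series, cm^2/s (length N).
#' @param k_series Labelled switch series (length >= N - 1).
#' @param circ Local-circulation series, cm^2/s (length >= N - 1).
#' @param away_mask Logical series, `TRUE` where the fish is more than one
#'   body length from every wall (length N).
#' @param dt Sampling period, s.
#' @param k0 Arbitrary positive scaling constant of the residuals; the
#'   reported `sigma` is `k0 * sigma_over_k0`.
#' @param min_n Minimum number of usable step pairs.
#' @return List with `alpha`, `beta`, `sigma_over_k0`, `sigma`, `kappa`,
#'   `k_r`, `nll`, `n_star`, `feller_active`, `convergence`.
#' @export
mle_sde_params <- function(gamma_l, gamma_r, k_series, circ, away_mask,
                           dt = 1 / 30, k0 = 1, min_n = 500) {
  n <- length(gamma_l)
  stopifnot(length(gamma_r) == n, k0 > 0)
  idx <- which(away_mask[-n] & away_mask[-1L] &
                 gamma_l[-n] > 1e-8 & gamma_r[-n] > 1e-8)
  n_star <- length(idx)
  if (n_star < min_n)
    stop(sprintf("only %d masked samples (need >= %d)", n_star, min_n),
         call. = FALSE)
  Xl <- gamma_l[idx]; Yl <- gamma_l[idx + 1L]
  Xr <- gamma_r[idx]; Yr <- gamma_r[idx + 1L]
  hyd <- k_series[idx] * circ[idx]

  # --- weighted least squares on the (linear) Euler drift for the init ---
  # responses: dGamma; coefs c = (alpha*beta*dt, (alpha+kappa)*dt,
  # kappa*dt, k_r*dt); design rows [1, -X_self, X_other, +/- hyd]
  resp <- c(Yl - Xl, Yr - Xr)
  has_hydro <- stats::sd(hyd) > 0
  des <- cbind(1, -c(Xl, Xr), c(Xr, Xl),
               if (has_hydro) c(hyd, -hyd) else NULL)
  wts <- 1 / c(Xl, Xr)
  wfit <- stats::lm.wfit(des, resp, wts)
  res_std <- wfit$residuals * sqrt(wts)
  sig2_0 <- mean(res_std^2) / dt
  if (!is.finite(sig2_0) || sig2_0 < 1e-12)
    stop("degenerate residual variance (sigma ~ 0 in the data)",
         call. = FALSE)
  cf <- wfit$coefficients
  cf[!is.finite(cf)] <- 0
  kappa0 <- cf[[3L]] / dt
  alpha0 <- cf[[2L]] / dt - kappa0
  beta0 <- if (is.finite(alpha0) && alpha0 > 0) cf[[1L]] / (alpha0 * dt)
           else mean(c(Xl, Xr))
  kr0 <- if (has_hydro) cf[[4L]] / dt else 1
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- 1
  if (!is.finite(beta0) || beta0 <= 0) beta0 <- mean(c(Xl, Xr))
  if (!is.finite(kappa0) || kappa0 <= 0) kappa0 <- 0.5
  if (!is.finite(kr0) || kr0 <= 0) kr0 <- 1
  frac0 <- min(max(sig2_0 / (2 * alpha0 * beta0), 1e-4), 1 - 1e-4)

  nll_fun <- function(p) {
    alpha <- exp(p[1L]); beta <- exp(p[2L])
    kappa <- exp(p[4L]); k_r <- exp(p[5L])
    sig2 <- 2 * alpha * beta * stats::plogis(p[3L])
    v <- sig2 / k0^2 * dt
    zl <- em_residual(Xl, Yl, Xr, hyd, +1, alpha, beta, kappa, k_r, dt, k0)
    zr <- em_residual(Xr, Yr, Xl, hyd, -1, alpha, beta, kappa, k_r, dt, k0)
    n_star * log(2 * pi * v) + (sum(zl^2) + sum(zr^2)) / (2 * v)
  }

  p0 <- c(log(alpha0), log(beta0), stats::qlogis(frac0),
          log(kappa0), log(kr0))
  # deterministic multistarts: WLS solution plus fixed perturbations
  starts <- list(p0,
                 p0 + c(0.5, 0.1, 0.5, 0.5, 0.5),
                 p0 - c(0.5, 0.1, 0.5, 0.5, 0.5),
                 p0 + c(-0.3, 0.05, -1.0, 0.3, -0.7),
                 p0 + c(0.3, -0.05, 1.0, -0.3, 0.7))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll_fun, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed to converge for every start", call. = FALSE)
  p <- best$par
  alpha <- exp(p[1L]); beta <- exp(p[2L])
  frac <- stats::plogis(p[3L])
  kappa <- exp(p[4L]); k_r <- exp(p[5L])
  sigma <- sqrt(2 * alpha * beta * frac)
  list(alpha = alpha, beta = beta, sigma_over_k0 = sigma / k0,
       sigma = sigma, kappa = kappa, k_r = k_r,
       nll = best$value, n_star = n_star,
       feller_active = frac > 0.999, convergence = best$convergence)
}

#' Four-step calibration of the visual wall parameters
#'
#' Fits the wall function `k_w / (c_wall * d + 1)` to wall-proximal turn
#' data: (i) retain `(phi, d)` pairs close to the reference cutoff curve
#' `g(phi) = a_g + b_g exp(-(phi/c_g)^2)` (`|g(phi) - d| < delta`,
#' `|phi| < phi0`) whose turn opposes the collision angle
#' (`sign(gamma_l - gamma_r) = -sign(phi)`); (ii) smooth the absolute
#' strength difference against `d` with a locally weighted regression
#' (5% span); (iii) fit the wall function to the smoothed values by
#' nonlinear least squares; (iv) replace `k_w` by the maximum single
#' vortex strength observed near walls if that is larger (the fit uses
#' the strength *difference*, which underestimates the per-vortex turn
#' amplitude). With fewer than 20 retained points the decay `c_wall`
#' cannot be resolved: it is returned as `NA` and `k_w` comes from step
#' (iv) alone.
#'
#' @param wall_df Data frame with columns `phi` (rad), `d` (cm), `gdiff`
#'   (`gamma_l - gamma_r`, cm^2/s) for samples within one body length of
#'   a wall.
#' @param max_gamma_near Maximum single vortex strength observed near
#'   walls, for the step-(iv) correction (optional).
#' @param delta,phi0 Cutoff tolerances (cm, rad).
#' @param a_g,b_g,c_g Reference-curve constants (cm, cm, rad).
#' @param span Locally weighted regression span (fraction of points; an
#'   effective floor of 10 points applies for small samples).
#' @return List with `k_w`, `c_wall` (may be `NA`), `n_retained`.
#' @export
calibrate_wall <- function(wall_df, max_gamma_near = NULL,
                           delta = 1, phi0 = 1,
                           a_g = 2.8, b_g = 27.2, c_g = 0.26,
                           span = 0.05) {
  if (is.null(wall_df) || nrow(wall_df) == 0)
    stop("no wall-proximal samples available", call. = FALSE)
  g <- a_g + b_g * exp(-(wall_df$phi / c_g)^2)
  keep <- abs(g - wall_df$d) < delta & abs(wall_df$phi) < phi0 &
    sign(wall_df$gdiff) == -sign(wall_df$phi) & wall_df$phi != 0
  pts <- wall_df[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 20) {
    if (is.null(max_gamma_near))
      stop("fewer than 20 retained wall points and no near-wall strengths ",
           "for the step-(iv) correction", call. = FALSE)
    return(list(k_w = max_gamma_near, c_wall = NA_real_, n_retained = n))
  }
  ord <- order(pts$d)
  d <- pts$d[ord]
  absg <- abs(pts$gdiff[ord])
  eff_span <- max(span, min(1, 10 / n))
  lo <- stats::loess(absg ~ d, span = eff_span, degree = 2,
                     control = stats::loess.control(surface = "direct",
                                                    iterations = 1))
  y_d <- stats::fitted(lo)
  y_d[y_d < 0] <- 0
  fit <- tryCatch(
    minpack.lm::nlsLM(y_d ~ kw / (cw * d + 1),
                      start = list(kw = max(y_d), cw = 1),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (is.null(max_gamma_near))
      stop("wall-function fit failed and no near-wall strengths available",
           call. = FALSE)
    return(list(k_w = max_gamma_near, c_wall = NA_real_, n_retained = n))
  }
  cf <- stats::coef(fit)
  k_w <- cf[["kw"]]
  if (!is.null(max_gamma_near)) k_w <- max(k_w, max_gamma_near)
  list(k_w = k_w, c_wall = cf[["cw"]], n_retained = n)
}

#' Extract wall-interaction points from a trajectory
#'
#' For every frame whose centroid lies within `bl` of a wall, computes the
#' projected wall encounter and pairs it with the estimated strength
#' difference; also reports the largest single vortex strength seen near
#' walls (used by the step-(iv) correction of [calibrate_wall()]).
#'
#' @param traj A [trajectory()].
#' @param strengths Output of [estimate_vortex_strengths()] for `traj`.
#' @param arena An [arena()].
#' @param bl Body length, cm.
#' @return List with `points` (data frame `phi, d, gdiff`) and
#'   `max_gamma_near`.
#' @export
wall_interaction_points <- function(traj, strengths, arena, bl = 3.6) {
  m <- nrow(strengths)
  near <- which(pmin(arena$x_max - abs(traj$x[seq_len(m)]),
                     arena$y_max - abs(traj$y[seq_len(m)])) < bl)
  if (!length(near))
    return(list(points = data.frame(phi = numeric(), d = numeric(),
                                    gdiff = numeric()),
                max_gamma_near = NULL))
  phi <- numeric(length(near)); d <- numeric(length(near))
  for (j in seq_along(near)) {
    i <- near[j]
    st <- list(x = min(max(traj$x[i], -arena$x_max), arena$x_max),
               y = min(max(traj$y[i], -arena$y_max), arena$y_max),
               theta = traj$theta[i])
    enc <- wall_geometry(st, arena)
    phi[j] <- enc$phi; d[j] <- enc$d
  }
  list(points = data.frame(
         phi = phi, d = d,
         gdiff = strengths$gamma_l[near] - strengths$gamma_r[near]),
       max_gamma_near = max(strengths$gamma_l[near],
                            strengths$gamma_r[near]))
}

#' Calibrate the full model from one trajectory
#'
#' Orchestrates the whole inverse pipeline: vortex strengths from inverse
#' kinematics, switch labelling from the synchronization error, Markov
#' switching rates, constrained maximum likelihood for
#' `(alpha, beta, sigma, kappa, k_r)` on the away-from-wall samples, and
#' the four-step wall calibration on the wall-proximal samples.
#'
#' @param traj A [trajectory()] (typically 9,000 samples or more).
#' @param profile A [flow_profile()].
#' @param arena An [arena()].
#' @param l Dipole width, cm.
#' @param r Sensing radius, cm.
#' @param k0 Residual scaling constant of the likelihood.
#' @param bl Body length, cm (wall mask threshold).
#' @param min_n Minimum masked sample count for the likelihood stage.
#' @return An object of class `calibration_result`: list with
#'   `theta_hat`, `lambda_hat`, `wall_hat`, `k_series`, `diagnostics`.
#' @export
calibrate_trial <- function(traj, profile, arena = rheodipole::arena(),
                            l = 0.5, r = 1.8, k0 = 1, bl = 3.6,
                            min_n = 500) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- stats::median(diff(traj$t))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  est <- stage("strengths", estimate_vortex_strengths(traj, profile, l))
  m <- nrow(est)
  circ <- local_circulation(profile, traj$y[seq_len(m)], r)
  k_series <- stage("labeling",
                    label_k_series(est$gamma_l - est$gamma_r, circ, dt = dt))
  lambda_hat <- stage("switch-rates", estimate_switch_rates(k_series, dt))
  away <- pmin(arena$x_max - abs(traj$x), arena$y_max - abs(traj$y)) > bl
  theta_hat <- stage("mle",
    mle_sde_params(est$gamma_l, est$gamma_r, k_series, circ,
                   away[seq_len(m)], dt = dt, k0 = k0, min_n = min_n))
  wip <- stage("wall-extract", wall_interaction_points(traj, est, arena, bl))
  wall_hat <- tryCatch(
    calibrate_wall(wip$points, wip$max_gamma_near),
    error = function(e) list(k_w = NA_real_, c_wall = NA_real_,
                             n_retained = 0L))
  structure(list(
    theta_hat = theta_hat,
    lambda_hat = lambda_hat,
    wall_hat = wall_hat,
    k_series = k_series,
    diagnostics = list(
      nll = theta_hat$nll, n_star = theta_hat$n_star,
      away_fraction = mean(away), n_negative = attr(est, "n_negative"),
      feller_active = theta_hat$feller_active)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  th <- x$theta_hat
  cat(sprintf("  alpha=%.3g  beta=%.3g  sigma=%.3g  kappa=%.3g  k_r=%.3g\n",
              th$alpha, th$beta, th$sigma, th$kappa, th$k_r))
  cat(sprintf("  lambda1=%.3g  lambda2=%.3g\n",
              x$lambda_hat[["lambda1"]], x$lambda_hat[["lambda2"]]))
  cat(sprintf("  wall: k_w=%.4g  c_wall=%.4g  (n_retained=%d)\n",
              x$wall_hat$k_w, x$wall_hat$c_wall, x$wall_hat$n_retained))
  cat(sprintf("  N*=%d  nll=%.4g  away=%.1f%%\n",
              x$diagnostics$n_star, x$diagnostics$nll,
              100 * x$diagnostics$away_fraction))
  invisible(x)
}

#' Aggregate per-trial wall parameters into a summary table
#'
#' Appends `Mean` and `Median` rows to a per-trial table of wall
#' parameters, ignoring undefined entries (trials with too few retained
#' points report no decay constant).
#'
#' @param df Data frame with columns `trial`, `k_w`, `c_wall` (`c_wall`
#'   may contain `NA`).
#' @return The table with `Mean` and `Median` rows appended (trial column
#'   becomes character).
#' @export
aggregate_wall_table <- function(df) {
  stopifnot(all(c("trial", "k_w", "c_wall") %in% names(df)))
  out <- data.frame(trial = as.character(df$trial),
                    k_w = df$k_w, c_wall = df$c_wall)
  rbind(out,
        data.frame(trial = "Mean",
                   k_w = mean(df$k_w, na.rm = TRUE),
                   c_wall = mean(df$c_wall, na.rm = TRUE)),
        data.frame(trial = "Median",
                   k_w = stats::median(df$k_w, na.rm = TRUE),
                   c_wall = stats::median(df$c_wall, na.rm = TRUE)))
}

#' Calibrated Bright-condition wall parameters
#'
#' The per-trial wall parameters of the 12 Bright trials as shipped with
#' the package (`inst/extdata/wall_params_bright.csv`); trials whose decay
#' constant could not be resolved carry `NA`.
#'
#' @return Data frame with columns `trial`, `k_w`, `c_wall`.
#' @export
wall_params_bright <- function() {
  path <- system.file("extdata", "wall_params_bright.csv",
                      package = "rheodipole", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
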