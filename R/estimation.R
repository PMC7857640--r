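#' Recover vortex-strength series from a tracked trajectory
#'
#' Inverse kinematics of the finite dipole. For each frame `k` the
#' flow-compensated displacements and turn rate are
#' \deqn{\tilde x_k = x_{k+1} - x_k - T (U(y_{r,k}) + U(y_{l,k})) / 2}
#' \deqn{\tilde y_k = y_{k+1} - y_k}
#' \deqn{\tilde\omega_k = \omega_k - (U(y_{r,k}) - U(y_{l,k}))/l \cos\theta_k}
#' with the flow evaluated at the two vortex positions, and the strengths
#' follow from
#' \deqn{\Gamma_{l,k} = \pi l\,((2/T)\sqrt{\tilde x_k^2+\tilde y_k^2} + l\tilde\omega_k)}
#' \deqn{\Gamma_{r,k} = \pi l\,((2/T)\sqrt{\tilde x_k^2+\tilde y_k^2} - l\tilde\omega_k)}
#' Negative outputs (possible when the turn term exceeds the speed term,
#' e.g. under tracking noise) are reported via the `n_negative` attribute,
#' never clipped.
#'
#' @param traj A [trajectory()] (uses columns `x, y, theta, omega`; if
#'   `omega` is absent it is computed as the wrapped per-step heading
#'   increment over `dt`).
#' @param profile A [flow_profile()].
#' @param l Dipole width, cm.
#' @return Data frame with columns `gamma_l`, `gamma_r` (`nrow(traj) - 1`
#'   rows) and attribute `n_negative`.
#' @export
estimate_vortex_strengths <- function(traj, profile, l = 0.5) {
  stopifnot(l > 0)
  n <- nrow(traj)
  if (n < 2) stop("trajectory too short", call. = FALSE)
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- stats::median(diff(traj$t))
  if (any(abs(diff(traj$t) - dt) > 1e-6))
    stop("trajectory is not uniformly sampled", call. = FALSE)
  k <- seq_len(n - 1L)
  x <- traj$x; y <- traj$y; th <- traj$theta
  om <- traj$omega
  if (is.null(om)) om <- c(wrap_angle(diff(th)) / dt, NA)
  off <- (l / 2) * cos(th[k])
  ul <- flow_velocity(profile, y[k] + off)
  ur <- flow_velocity(profile, y[k] - off)
  xt <- x[k + 1L] - x[k] - (ur + ul) * dt / 2
  yt <- y[k + 1L] - y[k]
  ot <- om[k] - (ur - ul) / l * cos(th[k])
  spd <- (2 / dt) * sqrt(xt^2 + yt^2)
  gl <- pi * l * (spd + l * ot)
  gr <- pi * l * (spd - l * ot)
  structure(data.frame(gamma_l = gl, gamma_r = gr),
            n_negative = sum(gl < 0) + sum(gr < 0))
}

#' Fit the background flow profile from swimming trajectories
#'
#' Inverts the axial kinematic equation at frames where the fish is not
#' swimming parallel to the flow (`|sin(theta)|` above a floor):
#' `U(y) = dx/dt - (dy/dt) cos(theta)/sin(theta)`, with forward-difference
#' velocities. Each trajectory's `(y, U)` cloud is fitted with a parabola
#' by least squares and the coefficients are averaged over trajectories.
#'
#' @param trajs A [trajectory()] or list of them.
#' @param l Dipole width, cm (unused by the inversion itself; kept for
#'   interface symmetry with [estimate_vortex_strengths()]).
#' @param sin_floor Minimum `|sin(theta)|` for a frame to be used; bounds
#'   the noise amplification of the cotangent term.
#' @param arena Optional [arena()]: when supplied, frames whose centroid
#'   touches the boundary are dropped (simulated trajectories clamp the
#'   position at walls, which corrupts the finite-difference velocity
#'   there; tracked fish never sit exactly on the wall).
#' @return A [flow_profile()] with the averaged coefficients.
#' @export
fit_flow_profile <- function(trajs, l = 0.5, sin_floor = 0.1, arena = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  coefs <- matrix(NA_real_, nrow = length(trajs), ncol = 2L)
  for (i in seq_along(trajs)) {
    traj <- trajs[[i]]
    n <- nrow(traj)
    dt <- attr(traj, "dt")
    if (is.null(dt)) dt <- stats::median(diff(traj$t))
    k <- seq_len(n - 1L)
    dxdt <- diff(traj$x) / dt
    dydt <- diff(traj$y) / dt
    th <- traj$theta[k]
    ok <- abs(sin(th)) > sin_floor
    if (!is.null(arena)) {
      tol <- 1e-9
      on_wall <- abs(traj$x) >= arena$x_max - tol |
        abs(traj$y) >= arena$y_max - tol
      ok <- ok & !on_wall[k] & !on_wall[k + 1L]
    }
    if (sum(ok) < 10) {
      warning(sprintf("trajectory %d: fewer than 10 usable frames; skipped", i))
      next
    }
    u <- dxdt[ok] - dydt[ok] * cos(th[ok]) / sin(th[ok])
    yy <- traj$y[k][ok]
    fit <- stats::lm.fit(cbind(yy^2, 1), u)
    coefs[i, ] <- fit$coefficients
  }
  if (all(is.na(coefs[, 1L])))
    stop("no trajectory had enough usable frames to fit the flow profile",
         call. = FALSE)
  cm <- colMeans(coefs, na.rm = TRUE)
  flow_profile(quad_coeff = cm[[1L]], const_coeff = cm[[2L]])
}
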