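#' Instantaneous state of the finite-dipole swimmer
#'
#' A fish is idealised as two point vortices (left, right) a fixed distance
#' `l` apart. The summed vortex strength sets the swimming speed, the
#' difference sets the turn rate. Heading `theta` lives in `[-pi, pi)`;
#' `theta = 0` is downstream (+X), `theta = -pi` upstream.
#'
#' @param x,y Centroid coordinates, cm.
#' @param theta Heading, rad; wrapped into `[-pi, pi)`.
#' @param gamma_l,gamma_r Left/right vortex circulation strengths, cm^2/s
#'   (non-negative).
#' @param k_switch Sensory-switch state, 0 (ignoring the local circulation)
#'   or 1 (following it).
#' @return An object of class `dipole_state`.
#' @export
dipole_state <- function(x = 0, y = 0, theta = -pi,
                         gamma_l = 0, gamma_r = 0, k_switch = 0L) {
  stopifnot(is.finite(x), is.finite(y), is.finite(theta),
            is.finite(gamma_l), is.finite(gamma_r),
            gamma_l >= 0, gamma_r >= 0, k_switch %in% c(0L, 1L))
  structure(list(x = x, y = y, theta = wrap_angle(theta),
                 gamma_l = gamma_l, gamma_r = gamma_r,
                 k_switch = as.integer(k_switch)),
            class = "dipole_state")
}

#' Wrap an angle into `[-pi, pi)`
#'
#' @param theta Angle(s), rad.
#' @return Wrapped angle(s) in the half-open interval `[-pi, pi)`.
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% can return 2*pi for values like -pi - eps due to rounding
  out[out >= pi] <- out[out >= pi] - 2 * pi
  out
}

#' Lateral positions of the two vortices
#'
#' The left vortex sits at `y + (l/2) cos(theta)` and the right one at
#' `y - (l/2) cos(theta)`; only the lateral offset matters in a uniaxial
#' flow.
#'
#' @param state A [dipole_state()].
#' @param l Dipole width (fish thickness), cm.
#' @return Named numeric vector `c(y_left =, y_right =)`, cm.
#' @export
vortex_lateral_positions <- function(state, l = 0.5) {
  stopifnot(l > 0)
  off <- (l / 2) * cos(state$theta)
  c(y_left = state$y + off, y_right = state$y - off)
}

#' Reduced (first-order) finite-dipole kinematics
#'
#' The governing ODEs obtained by Taylor-expanding the flow at the two
#' vortex locations about the centroid and keeping first order:
#' \deqn{dx/dt = (\Gamma_l+\Gamma_r)/(4\pi l)\cos\theta + U(y)}
#' \deqn{dy/dt = (\Gamma_l+\Gamma_r)/(4\pi l)\sin\theta}
#' \deqn{d\theta/dt = -U'(y)\cos^2\theta + (\Gamma_l-\Gamma_r)/(2\pi l^2)}
#' The background vorticity term rotates the fish while the strength
#' difference is its active steering control.
#'
#' @param state A [dipole_state()].
#' @param profile A [flow_profile()].
#' @param l Dipole width, cm.
#' @return Named numeric vector `c(dx =, dy =, dtheta =)` (cm/s, cm/s, rad/s).
#' @export
reduced_derivatives <- function(state, profile, l = 0.5) {
  stopifnot(l > 0)
  s <- state$gamma_l + state$gamma_r
  d <- state$gamma_l - state$gamma_r
  ct <- cos(state$theta)
  c(dx = s / (4 * pi * l) * ct + flow_velocity(profile, state$y),
    dy = s / (4 * pi * l) * sin(state$theta),
    dtheta = -flow_gradient(profile, state$y) * ct^2 + d / (2 * pi * l^2))
}

#' Exact two-vortex finite-dipole kinematics
#'
#' Evaluates the background flow at the two vortex positions rather than at
#' the centroid: `dx/dt` uses the mean of the two samples and `dtheta/dt`
#' uses their difference over `l` times `cos(theta)`. Retained as a
#' verification oracle for the reduced form: for a parabolic profile the
#' turn rates coincide exactly and the translational terms differ by
#' exactly `quad_coeff * (l/2)^2 * cos^2(theta)`.
#'
#' @inheritParams reduced_derivatives
#' @return Named numeric vector `c(dx =, dy =, dtheta =)`.
#' @export
exact_derivatives <- function(state, profile, l = 0.5) {
  stopifnot(l > 0)
  s <- state$gamma_l + state$gamma_r
  d <- state$gamma_l - state$gamma_r
  ct <- cos(state$theta)
  yy <- vortex_lateral_positions(state, l)
  ul <- flow_velocity(profile, yy[["y_left"]])
  ur <- flow_velocity(profile, yy[["y_right"]])
  c(dx = s / (4 * pi * l) * ct + (ur + ul) / 2,
    dy = s / (4 * pi * l) * sin(state$theta),
    dtheta = (ur - ul) / l * ct + d / (2 * pi * l^2))
}

#' Advance the kinematic state by one explicit Euler step
#'
#' Matches the Euler--Maruyama discretisation used for the vortex-strength
#' processes, so kinematics and stochastic dynamics share one time grid.
#'
#' @param state A [dipole_state()].
#' @param derivs Derivatives as returned by [reduced_derivatives()] or
#'   [exact_derivatives()].
#' @param dt Time step, s.
#' @return The advanced [dipole_state()] (heading re-wrapped).
#' @export
step_kinematics <- function(state, derivs, dt) {
  stopifnot(dt > 0)
  state$x <- state$x + derivs[["dx"]] * dt
  state$y <- state$y + derivs[["dy"]] * dt
  state$theta <- wrap_angle(state$theta + derivs[["dtheta"]] * dt)
  state
}
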