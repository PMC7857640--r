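#' Model constants of the multi-sensory control law
#'
#' Bundles every constant of the stochastic control model. The
#' Cox--Ingersoll--Ross (CIR) parameters must satisfy the Feller condition
#' `sigma^2 < 2 * alpha * beta`, which keeps the vortex strengths strictly
#' positive in continuous time; it is checked at construction.
#'
#' @param alpha Linear decay rate of the vortex strengths, 1/s.
#' @param beta Baseline vortex strength, cm^2/s. `beta / (2 pi l)` is the
#'   relative speed of the dipole during noise-free straight swimming.
#' @param sigma Noise intensity, cm/s.
#' @param kappa Diffusive coupling strength between the two vortices, 1/s
#'   (the ability to resume straight swimming after a maneuver).
#' @param k_r Hydrodynamic feedback gain weighting the sensed local
#'   circulation, 1/s.
#' @param lambda1 Switching rate from ignoring to following the local
#'   circulation, 1/s.
#' @param lambda2 Switching rate from following to ignoring it, 1/s.
#' @param k_w Visual wall-turn intensity, cm^2/s^2. `k_w = 0` encodes the
#'   Dark condition (no visual cues).
#' @param c_wall Spatial decay of the visual wall effect, 1/cm.
#' @param eta Tactile collision turn rate, cm^2/s^2.
#' @param epsilon Wall-contact tolerance, cm.
#' @param l Dipole width (fish thickness), cm.
#' @param r Lateral-line sensing radius, cm (half a body length).
#' @param bl Body length, cm; sets the wall-interaction range and the
#'   calibration mask.
#' @return An object of class `control_params`.
#' @export
control_params <- function(alpha = 1.0, beta = 10.0, sigma = 1.5,
                           kappa = 2.0, k_r = 5.0,
                           lambda1 = 0.3, lambda2 = 0.3,
                           k_w = 38.224, c_wall = 2.236,
                           eta = 10, epsilon = 0.001,
                           l = 0.5, r = 1.8, bl = 3.6) {
  vals <- list(alpha = alpha, beta = beta, sigma = sigma, kappa = kappa,
               k_r = k_r, lambda1 = lambda1, lambda2 = lambda2,
               k_w = k_w, c_wall = c_wall, eta = eta, epsilon = epsilon,
               l = l, r = r, bl = bl)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter `%s` must be a finite numeric scalar", nm),
           call. = FALSE)
  }
  if (k_w < 0) stop("`k_w` must be >= 0 (0 encodes Dark)", call. = FALSE)
  strict <- c("alpha", "beta", "sigma", "kappa", "k_r", "eta", "epsilon",
              "l", "r", "bl", "c_wall")
  for (nm in strict) if (vals[[nm]] <= 0)
    stop(sprintf("parameter `%s` must be strictly positive", nm), call. = FALSE)
  if (lambda1 < 0 || lambda2 < 0)
    stop("switching rates must be non-negative", call. = FALSE)
  if (!feller_check(alpha, beta, sigma))
    stop(sprintf(
      "Feller condition violated: sigma^2 = %.4g must be < 2*alpha*beta = %.4g",
      sigma^2, 2 * alpha * beta), call. = FALSE)
  structure(vals, class = "control_params")
}

#' @export
print.control_params <- function(x, ...) {
  cat("<control_params>\n")
  cat(sprintf("  CIR: alpha=%g 1/s, beta=%g cm^2/s, sigma=%g cm/s (Feller ok)\n",
              x$alpha, x$beta, x$sigma))
  cat(sprintf("  feedback: kappa=%g 1/s, k_r=%g 1/s, lambda=(%g, %g) 1/s\n",
              x$kappa, x$k_r, x$lambda1, x$lambda2))
  cat(sprintf("  wall: k_w=%g cm^2/s^2, c_wall=%g 1/cm, eta=%g, epsilon=%g cm\n",
              x$k_w, x$c_wall, x$eta, x$epsilon))
  cat(sprintf("  geometry: l=%g cm, r=%g cm, bl=%g cm\n", x$l, x$r, x$bl))
  invisible(x)
}

#' Rectangular test section
#'
#' The swimming arena `[-x_max, x_max] x [-y_max, y_max]`; defaults match
#' the 30 cm x 13.8 cm water-channel test section. `corner_size` is the
#' side of the square corner regions inside which the wall encounter is
#' frozen during simulation (avoids oscillations at the discontinuous
#' corners).
#'
#' @param x_max Half-length, cm.
#' @param y_max Half-width, cm.
#' @param corner_size Corner-square side, cm.
#' @return An object of class `arena`.
#' @export
arena <- function(x_max = 15.0, y_max = 6.9, corner_size = 1.0) {
  stopifnot(x_max > 0, y_max > 0, corner_size > 0)
  structure(list(x_max = x_max, y_max = y_max, corner_size = corner_size),
            class = "arena")
}

#' Diffusive coupling between the vortex strengths
#'
#' `kappa * (gamma_r - gamma_l)`: drives the pair toward the
#' synchronisation manifold `gamma_l == gamma_r` (straight swimming). The
#' value feeds the left strength with + sign and the right with - sign.
#'
#' @param gamma_l,gamma_r Vortex strengths, cm^2/s.
#' @param kappa Coupling strength, 1/s.
#' @return Feedback contribution, cm^2/s^2.
#' @export
coupling_feedback <- function(gamma_l, gamma_r, kappa) {
  stopifnot(kappa > 0)
  kappa * (gamma_r - gamma_l)
}

#' Hydromechanical feedback from the sensed local circulation
#'
#' `k_r * K * L_c`: when the sensory switch `K` is 1 the fish follows the
#' local circulation of the background flow; positive `L_c` then induces a
#' counterclockwise turn. With `K = 0` the cue is ignored.
#'
#' @param k_state Switch state, 0 or 1.
#' @param k_r Hydrodynamic gain, 1/s.
#' @param circulation Sensed local circulation `L_c`, cm^2/s.
#' @return Feedback contribution, cm^2/s^2.
#' @export
hydro_feedback <- function(k_state, k_r, circulation) {
  k_r * k_state * circulation
}

#' Advance the two-state sensory switch
#'
#' The switch is a continuous-time Markov chain with rate `lambda1` for
#' 0 -> 1 and `lambda2` for 1 -> 0. Transitions use the exact exponential
#' jump probabilities `1 - exp(-lambda * dt)` (equivalent to the Poisson
#' increment as `dt -> 0`, stabler at coarse steps).
#'
#' @param k_state Current state, 0 or 1.
#' @param lambda1,lambda2 Switching rates, 1/s.
#' @param dt Time step, s.
#' @return New state (integer 0 or 1); consumes one uniform deviate from
#'   the current RNG stream.
#' @export
step_switch <- function(k_state, lambda1, lambda2, dt) {
  if (lambda1 < 0 || lambda2 < 0)
    stop("switching rates must be non-negative", call. = FALSE)
  stopifnot(dt > 0, k_state %in% c(0L, 1L))
  if (dt * max(lambda1, lambda2) > 0.1)
    warning("dt * max(lambda1, lambda2) > 0.1: switch discretisation is coarse")
  p <- if (k_state == 0L) 1 - exp(-lambda1 * dt) else 1 - exp(-lambda2 * dt)
  if (stats::runif(1) < p) 1L - as.integer(k_state) else as.integer(k_state)
}

#' Projected wall encounter: distance and angle of collision
#'
#' Casts a ray from the centroid along the heading and finds the first
#' boundary it crosses. `d` is the distance along the ray ("projected
#' distance to collision"). `phi` in `[-pi/2, pi/2]` is the signed angle
#' from the wall axis to the heading: `|phi| = pi/2` for a perpendicular
#' approach, `phi = 0` parallel to the wall, and `phi > 0` when the fish
#' approaches with its right side toward the wall (a clockwise turn away).
#'
#' @param state A [dipole_state()] (centroid inside the arena).
#' @param arena An [arena()].
#' @return List with `d` (cm), `phi` (rad), and `wall_id` one of
#'   `"left"`, `"right"` (outlet), `"top"`, `"bottom"`.
#' @export
wall_geometry <- function(state, arena) {
  x <- state$x; y <- state$y; th <- state$theta
  if (abs(x) > arena$x_max + 1e-9 || abs(y) > arena$y_max + 1e-9)
    stop("centroid lies outside the arena", call. = FALSE)
  cth <- cos(th); sth <- sin(th)
  tx <- if (cth > 0) (arena$x_max - x) / cth
        else if (cth < 0) (-arena$x_max - x) / cth else Inf
  ty <- if (sth > 0) (arena$y_max - y) / sth
        else if (sth < 0) (-arena$y_max - y) / sth else Inf
  if (!is.finite(tx) && !is.finite(ty)) {
    # degenerate: heading magnitude zero cannot occur; keep a guard anyway
    return(list(d = min(arena$x_max - abs(x), arena$y_max - abs(y)),
                phi = 0, wall_id = "top"))
  }
  if (tx <= ty) {
    d <- tx
    wall_id <- if (cth > 0) "right" else "left"
    u <- c(if (cth > 0) 1 else -1, 0)   # outward normal
  } else {
    d <- ty
    wall_id <- if (sth > 0) "top" else "bottom"
    u <- c(0, if (sth > 0) 1 else -1)
  }
  h <- c(cth, sth)
  rhat <- c(sth, -cth)                  # fish's right-hand direction
  into <- max(-1, min(1, sum(h * u)))   # clamp for asin
  sgn <- sign(sum(rhat * u))
  if (sgn == 0) sgn <- 1                # perpendicular approach: phi = +pi/2
  list(d = max(d, 0), phi = sgn * asin(max(into, 0)), wall_id = wall_id)
}

#' Visual wall-avoidance feedback
#'
#' `k_w / (c_wall * d + 1) * sign(phi)`: intensity decays with the
#' projected distance to collision and the sign of the collision angle
#' selects the turn direction (away from the wall). `sign(0)` is defined
#' as 0 so a perfectly wall-parallel fish receives no lateral bias. In the
#' Dark condition `k_w = 0` and the term vanishes.
#'
#' @param enc A wall encounter from [wall_geometry()] (fields `d`, `phi`).
#' @param k_w Wall turn intensity, cm^2/s^2.
#' @param c_wall Wall decay, 1/cm.
#' @return Feedback contribution, cm^2/s^2.
#' @export
visual_wall_feedback <- function(enc, k_w, c_wall) {
  stopifnot(enc$d >= 0)
  k_w / (c_wall * enc$d + 1) * sign(enc$phi)
}

#' Total differential feedback input
#'
#' `u(t) = kappa (gamma_r - gamma_l) + u_h(t) + u_w(t)`. The sum enters
#' the left vortex-strength SDE with + sign and the right with - sign. The
#' visual wall term is active only when the centroid is within one body
#' length of a wall (the same threshold that splits the calibration data).
#'
#' @param state A [dipole_state()].
#' @param profile A [flow_profile()].
#' @param arena An [arena()].
#' @param params A [control_params()].
#' @param enc Optional precomputed wall encounter (used by the simulator
#'   to honour the corner freeze); computed from `state` if `NULL`.
#' @return Feedback `u`, cm^2/s^2.
#' @export
total_feedback <- function(state, profile, arena, params, enc = NULL) {
  u <- coupling_feedback(state$gamma_l, state$gamma_r, params$kappa) +
    hydro_feedback(state$k_switch, params$k_r,
                   local_circulation(profile, state$y, params$r))
  wall_dist <- min(arena$x_max - abs(state$x), arena$y_max - abs(state$y))
  if (wall_dist < params$bl) {
    if (is.null(enc)) enc <- wall_geometry(state, arena)
    u <- u + visual_wall_feedback(enc, params$k_w, params$c_wall)
  }
  u
}

#' Tactile collision update of the vortex strengths
#'
#' At wall contact (within `epsilon` of a boundary) the strengths are
#' driven apart at rate `eta` according to the sign of the collision angle
#' just before impact, producing a turn away from the wall. At the outlet
#' wall (`x > x_max - epsilon`) with the fish heading away from it
#' (`|theta| > pi/2`) both strengths instead increase by `eta * dt`
#' (repulsive boost countering the outlet suction).
#'
#' @param state A [dipole_state()].
#' @param params A [control_params()].
#' @param arena An [arena()].
#' @param dt Time step, s.
#' @param phi_before Collision angle at the previous time step, rad.
#' @return Named numeric vector `c(gamma_l =, gamma_r =)` (clipped at 0).
#' @export
tactile_collision_update <- function(state, params, arena, dt, phi_before) {
  stopifnot(dt > 0)
  gl <- state$gamma_l; gr <- state$gamma_r
  at_x <- abs(state$x) > arena$x_max - params$epsilon
  at_y <- abs(state$y) > arena$y_max - params$epsilon
  if (state$x > arena$x_max - params$epsilon && abs(state$theta) > pi / 2) {
    gl <- gl + params$eta * dt
    gr <- gr + params$eta * dt
  } else if (at_x || at_y) {
    s <- sign(phi_before)
    gl <- gl + params$eta * s * dt
    gr <- gr - params$eta * s * dt
  }
  c(gamma_l = max(gl, 0), gamma_r = max(gr, 0))
}
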