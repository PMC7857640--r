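#' Parabolic uniaxial flow profile
#'
#' Constructs the background flow of the swimming channel: a uniaxial,
#' time-invariant velocity field `U(y) = quad_coeff * y^2 + const_coeff`
#' directed along +X, with `y` the lateral coordinate measured from the
#' channel centerline. The default coefficients are the profile fitted to
#' adult-zebrafish trajectories in a 30 cm x 13.8 cm test section,
#' `U(Y) = -0.036 Y^2 + 1.584` (cm, cm/s).
#'
#' The profile is stored as exactly two coefficients; the fitted profile is
#' even in `y`, so no linear term is carried.
#'
#' @param quad_coeff Quadratic coefficient, units 1/(cm s).
#' @param const_coeff Centerline speed, units cm/s.
#' @return An object of class `flow_profile`.
#' @examples
#' fp <- flow_profile()
#' flow_velocity(fp, 0)     # 1.584 cm/s at the centerline
#' flow_gradient(fp, 2)     # -0.144 1/s
#' @export
flow_profile <- function(quad_coeff = -0.036, const_coeff = 1.584) {
  stopifnot(is.numeric(quad_coeff), length(quad_coeff) == 1L, is.finite(quad_coeff),
            is.numeric(const_coeff), length(const_coeff) == 1L, is.finite(const_coeff))
  structure(list(quad_coeff = quad_coeff, const_coeff = const_coeff),
            class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("<flow_profile> U(y) = %g y^2 + %g  [cm, cm/s]\n",
              x$quad_coeff, x$const_coeff))
  invisible(x)
}

check_lateral <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("lateral coordinate `y` must be finite numeric", call. = FALSE)
  y
}

#' Axial flow velocity at a lateral position
#'
#' @param profile A [flow_profile()].
#' @param y Lateral coordinate(s), cm. May lie outside the channel; the
#'   parabola is evaluated as-is (the fitted profile is slightly negative
#'   beyond the walls and is not clipped).
#' @return Axial speed(s), cm/s.
#' @export
flow_velocity <- function(profile, y) {
  check_lateral(y)
  profile$quad_coeff * y^2 + profile$const_coeff
}

#' Lateral gradient of the axial flow velocity
#'
#' `U'(y) = 2 * quad_coeff * y`, units 1/s.
#'
#' @inheritParams flow_velocity
#' @return Velocity gradient(s), 1/s.
#' @export
flow_gradient <- function(profile, y) {
  check_lateral(y)
  2 * profile$quad_coeff * y
}

#' Local circulation of the background flow around the fish perimeter
#'
#' The hydromechanical cue sensed through the lateral line: the line
#' integral of the background velocity around a circle of radius `r`
#' centered at the fish centroid. For a uniaxial flow this closed form is
#' `L_c = -pi * r^2 * U'(y)`, exact up to O(r^4) for general smooth
#' profiles and exact for parabolic ones. Positive values mean the flow
#' induces counterclockwise rotation.
#'
#' @inheritParams flow_velocity
#' @param r Sensing radius, cm (default half a body length, BL = 3.6 cm).
#' @return Circulation(s), cm^2/s.
#' @seealso [circulation_quadrature()] for the numerical line integral.
#' @export
local_circulation <- function(profile, y, r = 1.8) {
  check_lateral(y)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("sensing radius `r` must be a positive finite scalar", call. = FALSE)
  -pi * r^2 * flow_gradient(profile, y)
}

#' Numerical line-integral of the local circulation
#'
#' Evaluates `-r * integral_0^{2pi} U(y + r sin(phi)) sin(phi) dphi` by
#' composite trapezoid quadrature on the periodic integrand (spectrally
#' accurate). Serves as an independent oracle for [local_circulation()]:
#' the two agree to machine precision for parabolic profiles and to O(r^4)
#' for general smooth profiles.
#'
#' @inheritParams local_circulation
#' @param n_nodes Number of quadrature nodes (>= 16).
#' @param velocity_fun Optional function `U(y)`; defaults to the profile's
#'   parabola. Supplying a different function exercises the O(r^4)
#'   remainder of the closed form.
#' @return Circulation, cm^2/s.
#' @export
circulation_quadrature <- function(profile, y, r = 1.8, n_nodes = 512,
                                   velocity_fun = NULL) {
  check_lateral(y)
  stopifnot(length(y) == 1L)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("sensing radius `r` must be a positive finite scalar", call. = FALSE)
  if (n_nodes < 16) stop("`n_nodes` must be at least 16", call. = FALSE)
  if (is.null(velocity_fun)) velocity_fun <- function(yy) flow_velocity(profile, yy)
  # trapezoid on a periodic integrand: nodes 0..2pi, endpoints identified
  phi <- seq(0, 2 * pi, length.out = n_nodes + 1L)[-(n_nodes + 1L)]
  h <- 2 * pi / n_nodes
  -r * sum(velocity_fun(y + r * sin(phi)) * sin(phi)) * h
}
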