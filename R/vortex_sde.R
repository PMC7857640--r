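#' Feller positivity condition for the CIR process
#'
#' `TRUE` iff `sigma^2 < 2 * alpha * beta` (strict). Under this condition
#' the continuous-time Cox--Ingersoll--Ross process never reaches zero.
#'
#' @param alpha Decay rate, 1/s.
#' @param beta Baseline, cm^2/s.
#' @param sigma Noise intensity, cm/s.
#' @return Logical.
#' @export
feller_check <- function(alpha, beta, sigma) {
  stopifnot(alpha > 0, beta > 0, sigma >= 0)
  sigma^2 < 2 * alpha * beta
}

#' One Euler--Maruyama step of the coupled vortex-strength SDEs
#'
#' The vortex strengths follow coupled CIR processes with the differential
#' feedback `u`:
#' \deqn{\Gamma_l' = \Gamma_l + [\alpha(\beta-\Gamma_l) + u]\,dt +
#'   \sigma\sqrt{\Gamma_l}\sqrt{dt}\,\xi_l}
#' \deqn{\Gamma_r' = \Gamma_r + [\alpha(\beta-\Gamma_r) - u]\,dt +
#'   \sigma\sqrt{\Gamma_r}\sqrt{dt}\,\xi_r}
#' Positivity of the discrete chain uses full truncation: the state is
#' clipped at zero inside the square root and after the step (the standard
#' weakly convergent scheme; excursions below zero are rare when the
#' Feller condition holds at `dt = 1/30 s`).
#'
#' @param gamma_l,gamma_r Current strengths, cm^2/s.
#' @param u Differential feedback, cm^2/s^2 (enters left with +, right
#'   with -).
#' @param params A [control_params()] (uses `alpha`, `beta`, `sigma`).
#' @param dt Time step, s.
#' @param noise Numeric length-2 vector of standard normal deviates
#'   `(xi_l, xi_r)`; drawn from the current RNG stream if `NULL`.
#' @return Named numeric vector `c(gamma_l =, gamma_r =)`.
#' @export
em_step_vortices <- function(gamma_l, gamma_r, u, params, dt, noise = NULL) {
  if (!all(is.finite(c(gamma_l, gamma_r, u, dt))) || dt <= 0)
    stop("non-finite input to em_step_vortices", call. = FALSE)
  if (is.null(noise)) noise <- stats::rnorm(2)
  sq <- sqrt(dt)
  gl <- gamma_l + (params$alpha * (params$beta - gamma_l) + u) * dt +
    params$sigma * sqrt(max(gamma_l, 0)) * sq * noise[[1L]]
  gr <- gamma_r + (params$alpha * (params$beta - gamma_r) - u) * dt +
    params$sigma * sqrt(max(gamma_r, 0)) * sq * noise[[2L]]
  c(gamma_l = max(gl, 0), gamma_r = max(gr, 0))
}
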