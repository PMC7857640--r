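# Shared fixtures: the study flow profile, arena, and small helpers used
# across test files. All synthetic data is generated in code under fixed
# seeds.

paper_profile <- function() flow_profile(-0.036, 1.584)

study_arena <- function() arena(15, 6.9, 1)

# Simulate the coupled vortex pair alone (no walls, no kinematics), with
# feedback restricted to the diffusive coupling and an optional hydro term.
# Returns a matrix with columns gamma_l, gamma_r.
simulate_vortex_pair <- function(params, n_steps, dt = 1 / 30, seed = 1,
                                 hydro = 0) {
  set.seed(seed)
  g <- matrix(NA_real_, n_steps, 2)
  gl <- params$beta; gr <- params$beta
  for (i in seq_len(n_steps)) {
    u <- coupling_feedback(gl, gr, params$kappa) + hydro
    st <- em_step_vortices(gl, gr, u, params, dt)
    gl <- st[["gamma_l"]]; gr <- st[["gamma_r"]]
    g[i, 1] <- gl; g[i, 2] <- gr
  }
  colnames(g) <- c("gamma_l", "gamma_r")
  g
}

# Forward-integrate noise-free kinematics with constant strengths and wrap
# the result as a trajectory (omega recorded as the wrapped per-step
# heading increment, as the simulator and a tracker do).
integrate_kinematics <- function(state, profile, l, dt, n_steps) {
  x <- numeric(n_steps); y <- numeric(n_steps); th <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    x[i] <- state$x; y[i] <- state$y; th[i] <- state$theta
    state <- step_kinematics(state, reduced_derivatives(state, profile, l), dt)
  }
  om <- c(wrap_angle(diff(th)) / dt, 0)
  trajectory(data.frame(t = (seq_len(n_steps) - 1) * dt, x = x, y = y,
                        theta = th, omega = om,
                        gamma_l = state$gamma_l, gamma_r = state$gamma_r,
                        k = 0L),
             dt = dt)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
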