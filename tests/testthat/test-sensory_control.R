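test_that("control parameter validation enforces positivity and the Feller condition", {
  expect_s3_class(control_params(), "control_params")
  expect_error(control_params(alpha = 0.1, beta = 0.1, sigma = 1), "Feller")
  expect_error(control_params(alpha = -1), "positive")
  expect_error(control_params(k_w = -5), "k_w")
  # k_w = 0 encodes Dark and is legal
  expect_equal(control_params(k_w = 0)$k_w, 0)
})

test_that("coupling feedback vanishes on the synchronization manifold and opposes imbalance", {
  expect_equal(coupling_feedback(5, 5, 0.7), 0)
  expect_lt(coupling_feedback(10, 4, 0.5), 0)   # drives gamma_l down
  expect_equal(coupling_feedback(10, 4, 0.5), -3)
})

test_that("hydromechanical feedback is gated by the switch and linear in the cue", {
  expect_equal(hydro_feedback(0, 3, 100), 0)
  expect_gt(hydro_feedback(1, 2, 0.5), 0)
  expect_equal(hydro_feedback(1, 2, -1.5), -3)
})

test_that("sensory switch follows the two-state Markov law", {
  # zero rates: frozen
  set.seed(1)
  expect_equal(step_switch(0L, 0, 0, 1 / 30), 0L)
  expect_equal(step_switch(1L, 0, 0, 1 / 30), 1L)
  expect_error(step_switch(0L, -1, 1, 0.1), "non-negative")

  # stationary occupancy lambda1/(lambda1+lambda2) = 1/3 within 3 s.e.
  l1 <- 0.2; l2 <- 0.4; dt <- 0.1; n <- 150000
  set.seed(42)
  k <- integer(n); s <- 0L
  for (i in seq_len(n)) { s <- step_switch(s, l1, l2, dt); k[i] <- s }
  p_hat <- mean(k)
  n_eff <- n * dt * (l1 + l2)   # ~ one independent sample per mixing time
  se <- sqrt((1 / 3) * (2 / 3) / n_eff)
  expect_lt(abs(p_hat - 1 / 3), 3 * se)

  # dwell times are geometric with means 1/lambda
  r <- rle(k)
  expect_rel_error(mean(r$lengths[r$values == 0]) * dt, 1 / l1, 0.1)
  expect_rel_error(mean(r$lengths[r$values == 1]) * dt, 1 / l2, 0.1)

  # reproducible sample path
  set.seed(7); a <- replicate(50, step_switch(0L, 0.9, 0.9, 0.1))
  set.seed(7); b <- replicate(50, step_switch(0L, 0.9, 0.9, 0.1))
  expect_identical(a, b)
  # coarse discretisation is flagged
  expect_warning(step_switch(0L, 2, 2, 0.1), "coarse")
})

test_that("wall geometry returns the first boundary hit with the signed collision angle", {
  ar <- study_arena()
  # straight at the top wall from mid-channel
  enc <- wall_geometry(dipole_state(x = 0, y = 5.9, theta = pi / 2), ar)
  expect_equal(enc$wall_id, "top")
  expect_equal(enc$d, 1.0)
  expect_equal(abs(enc$phi), pi / 2)

  # parallel to the top wall: phi = 0 w.r.t. that wall, ray hits an end wall
  enc <- wall_geometry(dipole_state(x = 0, y = 6.5, theta = 0), ar)
  expect_equal(enc$wall_id, "right")
  expect_equal(enc$d, 15)
  expect_equal(abs(enc$phi), pi / 2)  # perpendicular to the end wall it hits

  # oblique approach to top wall: right side toward wall => phi > 0
  enc <- wall_geometry(dipole_state(x = 0, y = 6, theta = 3 * pi / 4), ar)
  expect_equal(enc$wall_id, "top")
  expect_gt(enc$phi, 0)
  # mirrored: left side toward wall => phi < 0
  enc2 <- wall_geometry(dipole_state(x = 0, y = 6, theta = pi / 4), ar)
  expect_lt(enc2$phi, 0)
  expect_equal(abs(enc2$phi), abs(enc$phi))

  expect_error(wall_geometry(dipole_state(x = 20, y = 0), ar), "outside")
})

test_that("visual wall feedback decays with distance and vanishes in the dark", {
  enc <- list(d = 1, phi = 0.4)
  expect_equal(visual_wall_feedback(enc, 0, 2.236), 0)          # Dark
  expect_equal(visual_wall_feedback(list(d = 0, phi = -0.2), 38.224, 2.236),
               -38.224)                                          # at contact
  expect_equal(visual_wall_feedback(enc, 38.224, 2.236), 38.224 / 3.236)
  expect_equal(visual_wall_feedback(list(d = 1, phi = 0), 38.224, 2.236), 0)
})

test_that("total feedback is the sum of its three parts and respects the 1-BL wall range", {
  fp <- paper_profile(); ar <- study_arena(); p <- control_params()
  # far from walls, balanced, switch off: all terms vanish
  st <- dipole_state(x = 0, y = 0, theta = 1, gamma_l = 5, gamma_r = 5)
  expect_equal(total_feedback(st, fp, ar, p), 0)

  # switch on at y > 0: upstream-turning (positive) hydro bias
  st <- dipole_state(x = 0, y = 2, theta = 1, gamma_l = 5, gamma_r = 5,
                     k_switch = 1L)
  expect_gt(total_feedback(st, fp, ar, p), 0)

  # additivity near a wall
  st <- dipole_state(x = 0, y = 4.5, theta = 2, gamma_l = 7, gamma_r = 4,
                     k_switch = 1L)
  enc <- wall_geometry(st, ar)
  expect_equal(total_feedback(st, fp, ar, p),
               coupling_feedback(7, 4, p$kappa) +
                 hydro_feedback(1, p$k_r, local_circulation(fp, 4.5, p$r)) +
                 visual_wall_feedback(enc, p$k_w, p$c_wall))

  # just outside the 1-BL band the wall term is absent
  st_far <- dipole_state(x = 0, y = 6.9 - 3.7, theta = 2,
                         gamma_l = 7, gamma_r = 4, k_switch = 1L)
  expect_equal(total_feedback(st_far, fp, ar, p),
               coupling_feedback(7, 4, p$kappa) +
                 hydro_feedback(1, p$k_r, local_circulation(fp, st_far$y, p$r)))
})

test_that("tactile collision rule drives strengths apart, except the repulsive outlet case", {
  ar <- study_arena(); p <- control_params()
  dt <- 1 / 30

  # away from walls: untouched
  st <- dipole_state(x = 0, y = 0, gamma_l = 5, gamma_r = 5)
  expect_equal(tactile_collision_update(st, p, ar, dt, 0.3),
               c(gamma_l = 5, gamma_r = 5))

  # side-wall contact: +/- eta * dt with the sign of the pre-impact angle
  st <- dipole_state(x = 0, y = 6.8995, theta = 1, gamma_l = 5, gamma_r = 5)
  out <- tactile_collision_update(st, p, ar, dt, phi_before = 0.7)
  expect_equal(out[["gamma_l"]], 5 + 10 / 30)
  expect_equal(out[["gamma_r"]], 5 - 10 / 30)

  # outlet wall, heading away: both strengths boosted
  st <- dipole_state(x = 14.9995, y = 0, theta = -pi, gamma_l = 5, gamma_r = 5)
  out <- tactile_collision_update(st, p, ar, dt, phi_before = -0.2)
  expect_equal(unname(out), c(5 + 10 * dt, 5 + 10 * dt))

  # clipping at zero
  st <- dipole_state(x = 0, y = 6.8995, theta = 1,
                     gamma_l = 0.1, gamma_r = 0.1)
  out <- tactile_collision_update(st, p, ar, dt, phi_before = -0.7)
  expect_equal(out[["gamma_l"]], 0)
})
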