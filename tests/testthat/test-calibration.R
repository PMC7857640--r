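test_that("switch labelling follows the synchronization-error and window rules", {
  n <- 300
  # perfectly synchronised slow signals: zero error, all labelled 1
  s <- sin(2 * pi * seq_len(n) / 600)
  expect_equal(label_k_series(3 * s, 0.5 * s), rep(1L, n))

  # anti-phase constants: error sqrt(2) everywhere, never labelled
  expect_equal(label_k_series(rep(-3, n), rep(2, n)), rep(0L, n))

  # synchronised run shorter than the 2-s window is rejected
  om <- rep(-1, n); om[100:129] <- 1
  expect_equal(label_k_series(om, rep(1, n)), rep(0L, n))
  # a long-enough run is kept (away from the smoothing-blurred edges)
  om2 <- rep(-1, n); om2[81:200] <- 1
  lab <- label_k_series(om2, rep(1, n))
  expect_true(all(lab[100:180] == 1L))
  expect_true(all(lab[c(1:80, 210:n)] == 0L))

  expect_error(label_k_series(rep(0, 10), rep(1, 10)), "all-zero")
  expect_error(label_k_series(1:3, 1:4), "equal length")
})

test_that("switch-rate estimation is the exact CTMC maximum-likelihood counting", {
  dt <- 1 / 30
  expect_equal(estimate_switch_rates(rep(0L, 100), dt),
               c(lambda1 = 0, lambda2 = NA_real_))
  expect_equal(estimate_switch_rates(rep(1L, 100), dt),
               c(lambda1 = NA_real_, lambda2 = 0))
  alt <- rep(c(0L, 1L), 50)
  expect_equal(unname(estimate_switch_rates(alt, dt)), c(30, 30),
               tolerance = 0.05)
  expect_error(estimate_switch_rates(1L, dt), "length")

  # consistency on simulated chains
  errs <- t(vapply(1:20, function(s) {
    set.seed(s)
    k <- integer(9000); cur <- 0L
    for (i in 1:9000) { cur <- step_switch(cur, 0.2, 0.4, dt); k[i] <- cur }
    est <- estimate_switch_rates(k, dt)
    c(abs(est[["lambda1"]] - 0.2) / 0.2, abs(est[["lambda2"]] - 0.4) / 0.4)
  }, numeric(2)))
  expect_lt(mean(errs[, 1]), 0.25)
  expect_lt(mean(errs[, 2]), 0.25)
})

# Simulate the discrete vortex-strength chain with a known latent switch
# series and circulation signal: the direct generative model of the
# likelihood.
simulate_mle_dataset <- function(p, n, dt = 1 / 30, seed = 1) {
  set.seed(seed)
  circ <- 2.4 * sin(2 * pi * seq_len(n) / 3000)
  k <- integer(n); cur <- 0L
  p1 <- 1 - exp(-p$lambda1 * dt); p2 <- 1 - exp(-p$lambda2 * dt)
  u01 <- stats::runif(n)
  gl <- numeric(n); gr <- numeric(n)
  cgl <- p$beta; cgr <- p$beta
  for (i in seq_len(n)) {
    k[i] <- cur
    gl[i] <- cgl; gr[i] <- cgr
    u <- p$kappa * (cgr - cgl) + p$k_r * cur * circ[i]
    st <- em_step_vortices(cgl, cgr, u, p, dt)
    cgl <- st[["gamma_l"]]; cgr <- st[["gamma_r"]]
    cur <- if (cur == 0L) { if (u01[i] < p1) 1L else 0L
           } else         { if (u01[i] < p2) 0L else 1L }
  }
  list(gamma_l = gl, gamma_r = gr, k = k, circ = circ)
}

test_that("likelihood recovers the generating SDE parameters from the known switch series", {
  p <- control_params()
  errs <- t(vapply(1:3, function(s) {
    d <- simulate_mle_dataset(p, 20000, seed = s)
    fit <- mle_sde_params(d$gamma_l, d$gamma_r, d$k, d$circ,
                          rep(TRUE, 20000))
    vapply(c("alpha", "beta", "sigma", "kappa", "k_r"),
           function(nm) abs(fit[[nm]] - p[[nm]]) / p[[nm]], numeric(1))
  }, numeric(5)))
  expect_true(all(apply(errs, 2, stats::median) <= 0.15))
})

test_that("negative log-likelihood is lower at the truth than at 2x-perturbed parameters", {
  p <- control_params()
  dt <- 1 / 30
  nll <- function(d, alpha, beta, sigma, kappa, k_r) {
    n <- length(d$gamma_l) - 1
    X <- cbind(d$gamma_l[1:n], d$gamma_r[1:n])
    Y <- cbind(d$gamma_l[2:(n + 1)], d$gamma_r[2:(n + 1)])
    hyd <- d$k[1:n] * d$circ[1:n]
    z <- function(Xs, Ys, Zs, hs)
      (Ys + Xs * (alpha * dt + kappa * dt - 1) - alpha * beta * dt -
         kappa * dt * Zs - hs * k_r * hyd * dt) / sqrt(Xs)
    v <- sigma^2 * dt
    zl <- z(X[, 1], Y[, 1], X[, 2], +1)
    zr <- z(X[, 2], Y[, 2], X[, 1], -1)
    n * log(2 * pi * v) + (sum(zl^2) + sum(zr^2)) / (2 * v)
  }
  wins <- vapply(1:10, function(s) {
    d <- simulate_mle_dataset(p, 3000, seed = 100 + s)
    nll(d, p$alpha, p$beta, p$sigma, p$kappa, p$k_r) <=
      nll(d, 2 * p$alpha, 2 * p$beta, 2 * p$sigma, 2 * p$kappa, 2 * p$k_r)
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("degenerate (noise-free) strength data is rejected by the likelihood stage", {
  p <- control_params()
  d <- simulate_mle_dataset(control_params(sigma = 1e-9), 2000, seed = 1)
  expect_error(mle_sde_params(d$gamma_l, d$gamma_r, d$k, d$circ,
                              rep(TRUE, 2000)),
               "degenerate")
  expect_error(mle_sde_params(d$gamma_l[1:100], d$gamma_r[1:100],
                              d$k[1:100], d$circ[1:100], rep(TRUE, 100)),
               "masked samples")
})

test_that("wall cutoff retains every point sampled exactly on the reference curve", {
  phi <- seq(-0.95, 0.95, length.out = 60)
  phi <- phi[phi != 0]
  d <- 2.8 + 27.2 * exp(-(phi / 0.26)^2)
  df <- data.frame(phi = phi, d = d, gdiff = -sign(phi) * 5)
  w <- calibrate_wall(df, max_gamma_near = 1)
  expect_equal(w$n_retained, length(phi))
})

test_that("wall calibration recovers generative parameters and handles sparse input", {
  fx <- generate_wall_fixture(38.224, 2.236, n_points = 400, noise_sd = 0,
                              seed = 3)
  w <- calibrate_wall(fx)
  expect_rel_error(w$k_w, 38.224, 0.10)
  expect_rel_error(w$c_wall, 2.236, 0.10)

  # moderate noise still recovers the scale
  fxn <- generate_wall_fixture(38.224, 2.236, n_points = 400, noise_sd = 1,
                               seed = 4)
  wn <- calibrate_wall(fxn)
  expect_rel_error(wn$k_w, 38.224, 0.25)

  # too few points: decay undefined, amplitude from the step-(iv) correction
  fx10 <- generate_wall_fixture(38.224, 2.236, n_points = 10, seed = 5)
  w10 <- calibrate_wall(fx10, max_gamma_near = 41)
  expect_equal(w10$k_w, 41)
  expect_true(is.na(w10$c_wall))
  expect_error(calibrate_wall(fx10), "step-\\(iv\\)")
  expect_error(calibrate_wall(fx10[0, ]), "no wall-proximal")
})

test_that("full-trajectory calibration recovers the CIR core and is deterministic", {
  p <- control_params()
  tr <- run_trial(p, paper_profile(), study_arena(), seed = 21,
                  total_s = 1800, keep_s = 1800)
  fit <- calibrate_trial(tr, paper_profile(), study_arena())
  expect_rel_error(fit$theta_hat$alpha, p$alpha, 0.15)
  expect_rel_error(fit$theta_hat$beta, p$beta, 0.10)
  expect_rel_error(fit$theta_hat$sigma, p$sigma, 0.10)
  expect_rel_error(fit$lambda_hat[["lambda1"]], p$lambda1, 0.30)
  expect_gt(fit$diagnostics$n_star, 500)
  expect_false(fit$diagnostics$feller_active)

  fit2 <- calibrate_trial(tr, paper_profile(), study_arena())
  expect_identical(fit$theta_hat, fit2$theta_hat)
  expect_identical(fit$k_series, fit2$k_series)
})

test_that("calibrated core parameters are stable under a slightly wider wall mask", {
  p <- control_params()
  tr <- run_trial(p, paper_profile(), study_arena(), seed = 22,
                  total_s = 1800, keep_s = 1800)
  f10 <- calibrate_trial(tr, paper_profile(), study_arena(), bl = 3.6)
  f12 <- calibrate_trial(tr, paper_profile(), study_arena(), bl = 1.2 * 3.6)
  f14 <- calibrate_trial(tr, paper_profile(), study_arena(), bl = 1.4 * 3.6)
  # cleanly identified core: tight stability
  for (nm in c("alpha", "beta", "sigma")) {
    expect_rel_error(f12$theta_hat[[nm]], f10$theta_hat[[nm]], 0.10)
    expect_rel_error(f14$theta_hat[[nm]], f10$theta_hat[[nm]], 0.10)
  }
  # parameters identified through the labelled switch proxy wander more
  # with the mask (their absolute level is attenuated; see the vignette)
  for (nm in c("kappa", "k_r")) {
    expect_rel_error(f12$theta_hat[[nm]], f10$theta_hat[[nm]], 0.5)
    expect_rel_error(f14$theta_hat[[nm]], f10$theta_hat[[nm]], 0.5)
  }
})

test_that("wall-parameter aggregation reproduces summary rows over partially defined trials", {
  df <- data.frame(trial = 1:4, k_w = c(10, 20, 30, 40),
                   c_wall = c(NA, 2, 4, NA))
  agg <- aggregate_wall_table(df)
  expect_equal(agg$k_w[agg$trial == "Mean"], 25)
  expect_equal(agg$k_w[agg$trial == "Median"], 25)
  expect_equal(agg$c_wall[agg$trial == "Mean"], 3)
  expect_equal(agg$c_wall[agg$trial == "Median"], 3)
})
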