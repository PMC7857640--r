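#' Construct a trajectory object
#'
#' A trajectory is a data frame of uniformly sampled kinematic states with
#' columns `t, x, y, theta, omega, gamma_l, gamma_r, k` (s, cm, cm, rad,
#' rad/s, cm^2/s, cm^2/s, 0/1) and metadata attributes `dt`, `condition`,
#' `seed`, and `params`.
#'
#' @param df Data frame with the eight trajectory columns.
#' @param dt Sampling period, s.
#' @param condition Condition label (e.g. `"bright"`, `"dark"`).
#' @param seed Seed used to generate the trajectory (or `NA`).
#' @param params The generating [control_params()] (or `NULL`).
#' @return An object of class `trajectory` (a data frame).
#' @export
trajectory <- function(df, dt = 1 / 30, condition = NA_character_,
                       seed = NA_integer_, params = NULL) {
  needed <- c("t", "x", "y", "theta", "omega", "gamma_l", "gamma_r", "k")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trajectory is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[needed]
  if (nrow(df) >= 2) {
    gaps <- diff(df$t)
    if (any(abs(gaps - dt) > 1e-6))
      stop("trajectory is not uniformly sampled at dt", call. = FALSE)
  }
  structure(df, dt = dt, condition = condition, seed = seed, params = params,
            class = c("trajectory", "data.frame"))
}

#' Simulate one in-silico rheotaxis trial
#'
#' Integrates the full model -- reduced dipole kinematics, coupled CIR
#' vortex strengths under the total feedback, two-state sensory switching,
#' visual and tactile wall interaction -- with an Euler--Maruyama scheme at
#' `dt = 1/30 s`. The trial runs for `total_s` seconds and only the last
#' `keep_s` seconds are retained (the discarded prefix is burn-in toward
#' the stationary regime); defaults (1800 s total, 300 s kept) yield
#' exactly 9,000 retained samples.
#'
#' Position is clamped to the arena boundary after each step; inside the
#' four corner squares the wall encounter `(d, phi)` is frozen at its
#' entry value; the tactile rule uses the collision angle of the previous
#' step. Initial conditions: centroid uniform over the interior 80% of the
#' arena, heading uniform on `[-pi, pi)`, both strengths at `beta`,
#' switch off. The recorded `omega` is the realised per-step heading
#' increment divided by `dt`, as a tracker would measure.
#'
#' @param params A [control_params()].
#' @param profile A [flow_profile()].
#' @param arena An [arena()].
#' @param seed Integer seed; the whole state sequence is a pure function
#'   of it.
#' @param total_s Total simulated time, s.
#' @param keep_s Retained tail duration, s.
#' @param dt Time step and sampling period, s.
#' @param condition Condition label stored in the metadata.
#' @return A [trajectory()] with `keep_s / dt` rows.
#' @export
run_trial <- function(params, profile, arena = rheodipole::arena(),
                      seed = 1L, total_s = 6 * 300, keep_s = 300,
                      dt = 1 / 30, condition = NA_character_) {
  if (!feller_check(params$alpha, params$beta, params$sigma))
    stop("Feller condition violated in `params`", call. = FALSE)
  stopifnot(total_s >= keep_s, keep_s > 0, dt > 0)
  n_tot <- round(total_s / dt)
  n_keep <- round(keep_s / dt)

  set.seed(as.integer(seed))
  xi <- matrix(stats::rnorm(2L * n_tot), ncol = 2L)
  uu <- stats::runif(n_tot)
  u_init <- stats::runif(3L)

  xmax <- arena$x_max; ymax <- arena$y_max; cs <- arena$corner_size
  alpha <- params$alpha; beta <- params$beta; sig <- params$sigma
  kap <- params$kappa; kr <- params$k_r
  l1 <- params$lambda1; l2 <- params$lambda2
  kw <- params$k_w; cw <- params$c_wall
  eta <- params$eta; eps <- params$epsilon
  l <- params$l; r <- params$r; bl <- params$bl
  lc_coef <- -pi * r^2 * 2 * profile$quad_coeff   # L_c = lc_coef * y
  q <- profile$quad_coeff; u0 <- profile$const_coeff
  p1 <- 1 - exp(-l1 * dt); p2 <- 1 - exp(-l2 * dt)
  sqdt <- sqrt(dt)

  # initial conditions
  x <- (u_init[1L] * 1.6 - 0.8) * xmax
  y <- (u_init[2L] * 1.6 - 0.8) * ymax
  th <- wrap_angle(u_init[3L] * 2 * pi - pi)
  gl <- beta; gr <- beta; K <- 0L

  X <- numeric(n_tot); Y <- numeric(n_tot); TH <- numeric(n_tot)
  OM <- numeric(n_tot); GL <- numeric(n_tot); GR <- numeric(n_tot)
  KS <- integer(n_tot)

  in_corner_prev <- FALSE
  d_fro <- NA_real_; phi_fro <- NA_real_
  phi_prev <- NA_real_

  for (k in seq_len(n_tot)) {
    # --- wall encounter (with corner freeze) -------------------------------
    in_corner <- abs(x) > xmax - cs && abs(y) > ymax - cs
    if (in_corner && in_corner_prev) {
      d <- d_fro; phi <- phi_fro
    } else {
      cth <- cos(th); sth <- sin(th)
      tx <- if (cth > 0) (xmax - x) / cth else if (cth < 0) (-xmax - x) / cth else Inf
      ty <- if (sth > 0) (ymax - y) / sth else if (sth < 0) (-ymax - y) / sth else Inf
      if (tx <= ty) {
        d <- max(tx, 0)
        ux <- if (cth > 0) 1 else -1
        into <- cth * ux
        sgn <- sign(sth * ux)
      } else {
        d <- max(ty, 0)
        uy <- if (sth > 0) 1 else -1
        into <- sth * uy
        sgn <- sign(-cth * uy)
      }
      if (sgn == 0) sgn <- 1
      phi <- sgn * asin(min(max(into, 0), 1))
      if (in_corner) { d_fro <- d; phi_fro <- phi }
    }
    in_corner_prev <- in_corner
    if (k == 1L) phi_prev <- phi

    # --- total feedback ----------------------------------------------------
    u <- kap * (gr - gl) + kr * K * lc_coef * y
    if (min(xmax - abs(x), ymax - abs(y)) < bl)
      u <- u + kw / (cw * d + 1) * sign(phi)

    # --- kinematics derivatives from the current state ---------------------
    cth <- cos(th)
    spd <- (gl + gr) / (4 * pi * l)
    dx <- spd * cth + q * y^2 + u0
    dy <- spd * sin(th)
    dth <- -2 * q * y * cth^2 + (gl - gr) / (2 * pi * l^2)

    # --- vortex SDE (Euler-Maruyama, full truncation) ----------------------
    gl_new <- gl + (alpha * (beta - gl) + u) * dt +
      sig * sqrt(max(gl, 0)) * sqdt * xi[k, 1L]
    gr_new <- gr + (alpha * (beta - gr) - u) * dt +
      sig * sqrt(max(gr, 0)) * sqdt * xi[k, 2L]

    # --- tactile collision rule (uses previous-step collision angle) -------
    if (x > xmax - eps && abs(th) > pi / 2) {
      gl_new <- gl_new + eta * dt
      gr_new <- gr_new + eta * dt
    } else if (abs(x) > xmax - eps || abs(y) > ymax - eps) {
      s <- sign(phi_prev)
      gl_new <- gl_new + eta * s * dt
      gr_new <- gr_new - eta * s * dt
    }
    gl_new <- max(gl_new, 0); gr_new <- max(gr_new, 0)

    # --- advance, clamp, switch -------------------------------------------
    th_new <- wrap_angle(th + dth * dt)
    om <- wrap_angle(th_new - th) / dt
    x_new <- min(max(x + dx * dt, -xmax), xmax)
    y_new <- min(max(y + dy * dt, -ymax), ymax)
    K_new <- if (K == 0L) { if (uu[k] < p1) 1L else 0L
             } else       { if (uu[k] < p2) 0L else 1L }

    X[k] <- x; Y[k] <- y; TH[k] <- th; OM[k] <- om
    GL[k] <- gl; GR[k] <- gr; KS[k] <- K
    if (!all(is.finite(c(x_new, y_new, th_new, gl_new, gr_new))))
      stop(sprintf("integration failure (non-finite state) at step %d", k),
           call. = FALSE)
    x <- x_new; y <- y_new; th <- th_new
    gl <- gl_new; gr <- gr_new; K <- K_new
    phi_prev <- phi
  }

  idx <- (n_tot - n_keep + 1L):n_tot
  df <- data.frame(t = (seq_len(n_keep) - 1L) * dt,
                   x = X[idx], y = Y[idx], theta = TH[idx], omega = OM[idx],
                   gamma_l = GL[idx], gamma_r = GR[idx], k = KS[idx])
  trajectory(df, dt = dt, condition = condition, seed = as.integer(seed),
             params = params)
}

#' Default population statistics for parameter sampling
#'
#' Per-parameter mean and standard deviation used to draw trial-level
#' parameter sets. `alpha, sigma, kappa, k_r, lambda1, lambda2` are pooled
#' across conditions; `beta` is condition-specific (fish in the dark swim
#' faster relative to the flow). Wall parameters take the calibrated
#' Bright-condition means (`k_w = 38.224`, `c_wall = 2.236`); the Dark
#' condition forces `k_w = 0`. See the methods vignette for the rationale
#' behind each value.
#'
#' @return Data frame with columns `param`, `mean`, `sd`.
#' @export
default_param_stats <- function() {
  data.frame(
    param = c("alpha", "beta_bright", "beta_dark", "sigma", "kappa",
              "k_r", "lambda1", "lambda2", "k_w", "c_wall"),
    mean = c(1.0, 10.0, 16.0, 1.5, 2.0, 5.0, 0.3, 0.3, 38.224, 2.236),
    sd   = c(0.2, 1.5, 2.0, 0.2, 0.3, 0.8, 0.05, 0.05, 0, 0)
  )
}

#' Draw one trial-level parameter set from population statistics
#'
#' Draws each parameter from its Gaussian population distribution and
#' redraws until the set is positive and satisfies the Feller condition.
#' `beta` uses the row matching the condition (`beta_bright` or
#' `beta_dark`); in Dark, `k_w` is forced to 0 (no visual wall term).
#'
#' @param stats Data frame as returned by [default_param_stats()].
#' @param condition `"bright"` or `"dark"`.
#' @param max_draws Redraw limit before failing.
#' @param ... Fixed parameters passed through to [control_params()]
#'   (e.g. `eta`, `epsilon`, `l`, `r`, `bl`).
#' @return A [control_params()]; consumes deviates from the current RNG
#'   stream.
#' @export
sample_population_params <- function(stats = default_param_stats(),
                                     condition = c("bright", "dark"),
                                     max_draws = 1000, ...) {
  condition <- match.arg(condition)
  get_row <- function(p) {
    i <- match(p, stats$param)
    if (is.na(i)) stop("missing population statistics for `", p, "`",
                       call. = FALSE)
    stats[i, ]
  }
  draw1 <- function(p) {
    row <- get_row(p)
    stats::rnorm(1, row$mean, row$sd)
  }
  beta_key <- paste0("beta_", condition)
  for (i in seq_len(max_draws)) {
    alpha <- draw1("alpha"); beta <- draw1(beta_key); sigma <- draw1("sigma")
    kappa <- draw1("kappa"); k_r <- draw1("k_r")
    lambda1 <- draw1("lambda1"); lambda2 <- draw1("lambda2")
    k_w <- if (condition == "dark") 0 else abs(draw1("k_w"))
    c_wall <- abs(draw1("c_wall"))
    if (c_wall <= 0) c_wall <- get_row("c_wall")$mean
    ok <- all(c(alpha, beta, sigma, kappa, k_r) > 0) &&
      lambda1 >= 0 && lambda2 >= 0 && feller_check(alpha, beta, sigma)
    if (ok)
      return(control_params(alpha = alpha, beta = beta, sigma = sigma,
                            kappa = kappa, k_r = k_r,
                            lambda1 = lambda1, lambda2 = lambda2,
                            k_w = k_w, c_wall = c_wall, ...))
  }
  stop("could not draw a positive, Feller-satisfying parameter set in ",
       max_draws, " attempts", call. = FALSE)
}

#' Run a full in-silico experiment
#'
#' Replicates the experimental design: `n_trials_per_condition` trials in
#' Bright and as many in Dark, each with its own parameter draw and
#' derived seed, each simulated by [run_trial()].
#'
#' @param stats Population statistics, see [default_param_stats()].
#' @param profile A [flow_profile()].
#' @param arena An [arena()].
#' @param n_trials_per_condition Trials per condition (12 in the study).
#' @param seed Master seed; per-trial seeds are derived from it.
#' @param ... Passed to [run_trial()] (e.g. `total_s`, `keep_s`).
#' @return List of [trajectory()] objects, Bright trials first.
#' @export
run_experiment <- function(stats = default_param_stats(),
                           profile = flow_profile(),
                           arena = rheodipole::arena(),
                           n_trials_per_condition = 12, seed = 1L, ...) {
  stopifnot(n_trials_per_condition >= 1)
  n <- n_trials_per_condition
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(.Machine$integer.max, 2L * n)
  conds <- rep(c("bright", "dark"), each = n)
  param_sets <- lapply(seq_len(2L * n), function(i)
    sample_population_params(stats, conds[i]))
  lapply(seq_len(2L * n), function(i)
    run_trial(param_sets[[i]], profile, arena, seed = trial_seeds[i],
              condition = conds[i], ...))
}
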