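#' Default layered configuration
#'
#' One nested list covering every tunable of the model, with defaults
#' equal to the study constants: flow profile `-0.036 y^2 + 1.584`
#' (cm, cm/s), 30 cm x 13.8 cm test section, `dt = 1/30 s`, tactile
#' constants `eta = 10 cm^2/s^2`, `epsilon = 0.001 cm`, the wall-cutoff
#' curve (`phi0 = 1`, `a_g = 2.8`, `b_g = 27.2`, `c_g = 0.26`,
#' `delta = 1`), the labelling rule (threshold 0.35, 2 s window) and the
#' 1-BL masks.
#'
#' @return Nested list with blocks `flow`, `fish`, `arena`, `control`,
#'   `wall`, `labeling`, `experiment`.
#' @export
default_config <- function() {
  list(
    flow = list(quad_coeff = -0.036, const_coeff = 1.584),
    fish = list(l = 0.5, r = 1.8, bl = 3.6),
    arena = list(x_max = 15.0, y_max = 6.9, corner_size = 1.0),
    control = list(alpha = 1.0, beta = 10.0, sigma = 1.5, kappa = 2.0,
                   k_r = 5.0, lambda1 = 0.3, lambda2 = 0.3),
    wall = list(k_w = 38.224, c_wall = 2.236, eta = 10, epsilon = 0.001,
                phi0 = 1, a_g = 2.8, b_g = 27.2, c_g = 0.26, delta = 1),
    labeling = list(threshold = 0.35, window_s = 2, smooth_n = 15),
    experiment = list(dt = 1 / 30, total_s = 1800, keep_s = 300,
                      n_trials_per_condition = 12, k0 = 1)
  )
}

#' Read a configuration file (YAML), layered over the defaults
#'
#' Any block or field absent from the file keeps its default value.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  for (block in names(user)) {
    if (!block %in% names(cfg))
      stop("unknown config block: ", block, call. = FALSE)
    for (field in names(user[[block]])) {
      if (!field %in% names(cfg[[block]]))
        stop(sprintf("unknown config field: %s.%s", block, field),
             call. = FALSE)
      cfg[[block]][[field]] <- user[[block]][[field]]
    }
  }
  cfg
}

#' Build model objects from a configuration
#'
#' @param cfg Configuration list from [read_config()].
#' @return List with `params` ([control_params()]), `profile`
#'   ([flow_profile()]), `arena` ([arena()]).
#' @export
config_objects <- function(cfg = default_config()) {
  list(
    params = control_params(
      alpha = cfg$control$alpha, beta = cfg$control$beta,
      sigma = cfg$control$sigma, kappa = cfg$control$kappa,
      k_r = cfg$control$k_r, lambda1 = cfg$control$lambda1,
      lambda2 = cfg$control$lambda2, k_w = cfg$wall$k_w,
      c_wall = cfg$wall$c_wall, eta = cfg$wall$eta,
      epsilon = cfg$wall$epsilon, l = cfg$fish$l, r = cfg$fish$r,
      bl = cfg$fish$bl),
    profile = flow_profile(cfg$flow$quad_coeff, cfg$flow$const_coeff),
    arena = arena(cfg$arena$x_max, cfg$arena$y_max, cfg$arena$corner_size)
  )
}

#' End-to-end parameter-recovery harness
#'
#' Generates a ground-truth dataset with known parameters, runs the full
#' calibration on every trial, and reports per-parameter recovery: the
#' median estimate, the median relative error and its dispersion across
#' trials. Trials are simulated with the full duration retained so the
#' likelihood stage sees the intended sample count.
#'
#' @param params Ground-truth [control_params()].
#' @param profile A [flow_profile()].
#' @param arena An [arena()].
#' @param n_trials Number of replicate trials (>= 1).
#' @param seed Master seed.
#' @param total_s Simulated (and retained) duration per trial, s.
#' @return List with `report` (data frame: param, truth, median_est,
#'   median_rel_err, iqr_rel_err) and `fits` (per-trial
#'   `calibration_result`s); flags constraint-active fits.
#' @export
recover_parameters <- function(params, profile = flow_profile(),
                               arena = rheodipole::arena(),
                               n_trials = 10, seed = 1L, total_s = 1800) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  ds <- generate_ground_truth_dataset(params, profile, arena,
                                      n_trials = n_trials, seed = seed,
                                      total_s = total_s, keep_s = total_s)
  fits <- lapply(ds$trajectories, function(tr)
    calibrate_trial(tr, profile, arena, l = params$l, r = params$r,
                    bl = params$bl))
  pull <- function(f, nm) {
    switch(nm,
           lambda1 = f$lambda_hat[["lambda1"]],
           lambda2 = f$lambda_hat[["lambda2"]],
           f$theta_hat[[nm]])
  }
  param_names <- c("alpha", "beta", "sigma", "kappa", "k_r",
                   "lambda1", "lambda2")
  rows <- lapply(param_names, function(nm) {
    truth <- params[[nm]]
    est <- vapply(fits, pull, numeric(1), nm = nm)
    rel <- abs(est - truth) / abs(truth)
    q <- stats::quantile(rel, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
    data.frame(param = nm, truth = truth,
               median_est = stats::median(est, na.rm = TRUE),
               median_rel_err = stats::median(rel, na.rm = TRUE),
               iqr_rel_err = q[2L] - q[1L])
  })
  report <- do.call(rbind, rows)
  n_active <- sum(vapply(fits, function(f)
    isTRUE(f$diagnostics$feller_active), logical(1)))
  if (n_active > 0)
    message(n_active, " fit(s) ended with the Feller constraint active")
  list(report = report, fits = fits, n_feller_active = n_active)
}
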