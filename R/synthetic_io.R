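#' Generate a ground-truth dataset for recovery studies
#'
#' Runs [run_trial()] `n_trials` times with derived seeds and returns the
#' trajectories alongside the generating parameters. Simulated
#' trajectories carry the latent series (true `gamma_l`, `gamma_r`, `k`)
#' as columns, so every stage of the calibration pipeline can be checked
#' against known truth.
#'
#' @param params A [control_params()] (the ground truth).
#' @param profile A [flow_profile()].
#' @param arena An [arena()].
#' @param n_trials Number of trials.
#' @param seed Master seed; per-trial seeds are derived from it.
#' @param ... Passed to [run_trial()] (e.g. `total_s`, `keep_s`).
#' @return List with `trajectories`, `truth` (the parameters), `seeds`.
#' @export
generate_ground_truth_dataset <- function(params, profile = flow_profile(),
                                          arena = rheodipole::arena(),
                                          n_trials = 1, seed = 1L, ...) {
  if (!feller_check(params$alpha, params$beta, params$sigma))
    stop("Feller condition violated in `params`", call. = FALSE)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_trials)
  trajs <- lapply(seq_len(n_trials), function(i)
    run_trial(params, profile, arena, seed = seeds[i], ...))
  list(trajectories = trajs, truth = params, seeds = seeds)
}

#' Generate a synthetic wall-interaction fixture
#'
#' Samples `(phi, d)` pairs inside the retained region of the wall
#' calibration cutoff (near the reference curve `g(phi)`, `|phi| < phi0`)
#' and strength differences of magnitude `k_w / (c_wall * d + 1)` plus
#' Gaussian noise, signed `-sign(phi)`. With `noise_sd = 0`,
#' [calibrate_wall()] recovers `(k_w, c_wall)` up to smoothing and solver
#' tolerance.
#'
#' @param k_w,c_wall Generating wall parameters (cm^2/s^2, 1/cm).
#' @param n_points Number of samples.
#' @param noise_sd Gaussian noise on the magnitude, cm^2/s.
#' @param seed Integer seed.
#' @param phi0,a_g,b_g,c_g,delta Cutoff-region constants, as in
#'   [calibrate_wall()].
#' @return Data frame with columns `phi`, `d`, `gdiff`.
#' @export
generate_wall_fixture <- function(k_w, c_wall, n_points = 200,
                                  noise_sd = 0, seed = 1L,
                                  phi0 = 1, a_g = 2.8, b_g = 27.2,
                                  c_g = 0.26, delta = 1) {
  stopifnot(k_w > 0, c_wall > 0, n_points >= 0, noise_sd >= 0)
  if (n_points == 0)
    return(data.frame(phi = numeric(), d = numeric(), gdiff = numeric()))
  set.seed(as.integer(seed))
  phi <- stats::runif(n_points, -phi0, phi0)
  phi[phi == 0] <- 1e-6
  g <- a_g + b_g * exp(-(phi / c_g)^2)
  d <- pmax(g + stats::runif(n_points, -0.9 * delta, 0.9 * delta), 0)
  mag <- pmax(k_w / (c_wall * d + 1) + stats::rnorm(n_points, 0, noise_sd), 0)
  data.frame(phi = phi, d = d, gdiff = -sign(phi) * mag)
}

#' Write a trajectory to delimited text
#'
#' One row per sample, header `t,x,y,theta,omega,gamma_l,gamma_r,k`
#' (units s, cm, rad; cgs throughout), plus a JSON sidecar
#' `<path>.json` holding the metadata (sampling period, condition, seed,
#' generating parameters).
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  params <- attr(traj, "params")
  meta <- list(dt = attr(traj, "dt"),
               condition = attr(traj, "condition"),
               seed = attr(traj, "seed"),
               params = if (is.null(params)) NULL else unclass(params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory from delimited text
#'
#' Reads the CSV dialect of [write_trajectory()] (metadata sidecar picked
#' up automatically when present). External dialects with different
#' column names are supported through `mapping`; missing columns or a gap
#' in the time base raise a format error naming the defect.
#'
#' @param path CSV path.
#' @param mapping Optional named character vector mapping standard column
#'   names to the file's names, e.g.
#'   `c(x = "centroid_x", theta = "heading")`.
#' @param dt Expected sampling period, s (used when no sidecar exists).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, mapping = NULL, dt = 1 / 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      src <- mapping[[std]]
      if (!src %in% names(df))
        stop(sprintf("format error: mapped column `%s` (for `%s`) not in file",
                     src, std), call. = FALSE)
      names(df)[names(df) == src] <- std
    }
  }
  needed <- c("t", "x", "y", "theta", "omega", "gamma_l", "gamma_r", "k")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta_path <- paste0(path, ".json")
  condition <- NA_character_; seed <- NA_integer_; params <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$dt)) dt <- meta$dt
    if (!is.null(meta$condition)) condition <- meta$condition
    if (!is.null(meta$seed)) seed <- as.integer(meta$seed)
    if (!is.null(meta$params))
      params <- do.call(control_params, as.list(meta$params))
  }
  if (nrow(df) >= 2 && any(abs(diff(df$t) - dt) > 1e-6))
    stop("format error: non-uniform timestamps (gap in `t`)", call. = FALSE)
  trajectory(df, dt = dt, condition = condition, seed = seed, params = params)
}
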