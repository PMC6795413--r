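#' Twin-experiment configuration
#'
#' Emulates the two-stream observing system of an operational coastal
#' assimilation cycle at column scale: one state variable observed densely
#' and gaplessly at the surface (the role played by a gapless sea-surface
#' temperature product), and surface chlorophyll observed sparsely, with a
#' contiguous block of time slots removed as a cloud-cover analog. All
#' randomness (truth perturbation, observation noise, mask placement)
#' derives from the single `seed`.
#'
#' @param perturb_scale relative scale of the (lognormal) multiplicative
#'   perturbation turning the background into the synthetic truth initial
#'   condition.
#' @param noise_dense,noise_chl additive Gaussian observation noise standard
#'   deviations for the dense stream (mmol N m^-3) and chlorophyll
#'   (mg chl m^-3); also used as the assimilation error stds R (perfectly
#'   specified errors), floored at 1e-6 to keep R positive definite when a
#'   noise-free stream is requested.
#' @param mask_fraction fraction of chlorophyll time slots removed as one
#'   contiguous block, in [0, 1).
#' @param dense_quantity the densely observed state variable.
#' @param obs_every observation interval in model steps.
#' @param seed integer RNG seed.
#' @return A list of class `"twin_config"`.
#' @export
twin_config <- function(perturb_scale = 0.2, noise_dense = 0.1, noise_chl = 0.05,
                        mask_fraction = 0.4, dense_quantity = "NO3",
                        obs_every = 6, seed = 0) {
  stopifnot(perturb_scale >= 0, noise_dense >= 0, noise_chl >= 0,
            mask_fraction >= 0, mask_fraction < 1, obs_every >= 1)
  if (!dense_quantity %in% nemuro_variables())
    stop(sprintf("twin_config: unknown dense quantity '%s'", dense_quantity), call. = FALSE)
  structure(list(perturb_scale = perturb_scale, noise_dense = noise_dense,
                 noise_chl = noise_chl, mask_fraction = mask_fraction,
                 dense_quantity = dense_quantity, obs_every = as.integer(obs_every),
                 seed = as.integer(seed)),
            class = "twin_config")
}

#' Generate synthetic observations from a truth trajectory
#'
#' Samples the dense quantity at the surface cell at every observation time
#' with additive Gaussian noise, and surface chlorophyll at the same times
#' with one contiguous block of slots removed (`mask_fraction` of them) and
#' noise added. Fully reproducible from the seed.
#'
#' @param truth_trajectory n x (window+1) state matrix from
#'   [run_trajectory()].
#' @param config a [twin_config()].
#' @param params [nemuro_params()] (for the chlorophyll diagnostic).
#' @param index the model's [state_index()].
#' @return Observation data frame (time, cell, quantity, value, sigma) with
#'   attributes `"seed"` and `"mask_fraction"`.
#' @export
generate_observations <- function(truth_trajectory, config, params, index) {
  window <- ncol(truth_trajectory) - 1L
  times <- seq(config$obs_every, window, by = config$obs_every)
  if (!length(times))
    stop("generate_observations: the window is shorter than one observation interval", call. = FALSE)
  surf <- 1L
  pos_dense <- flat_index(index, config$dense_quantity, surf)
  pos_ps <- flat_index(index, "PS", surf)
  pos_pl <- flat_index(index, "PL", surf)
  n_slots <- length(times)
  n_mask <- floor(config$mask_fraction * n_slots)
  local_seed(config$seed, {
    keep <- rep(TRUE, n_slots)
    if (n_mask > 0) {
      start <- sample.int(n_slots - n_mask + 1L, 1L)
      keep[start:(start + n_mask - 1L)] <- FALSE
    }
    dense <- data.frame(
      time = times, cell = surf, quantity = config$dense_quantity,
      value = truth_trajectory[pos_dense, times + 1L] +
        config$noise_dense * stats::rnorm(n_slots),
      sigma = max(config$noise_dense, 1e-6))
    chl_truth <- params$chl2n * (truth_trajectory[pos_ps, times + 1L] +
                                 truth_trajectory[pos_pl, times + 1L])
    chl <- data.frame(
      time = times, cell = surf, quantity = "chlorophyll",
      value = chl_truth + config$noise_chl * stats::rnorm(n_slots),
      sigma = max(config$noise_chl, 1e-6))
    obs <- rbind(dense, chl[keep, , drop = FALSE])
    rownames(obs) <- NULL
    structure(obs, seed = config$seed, mask_fraction = config$mask_fraction)
  })
}

#' Model-improvement metric at the observation locations
#'
#' Per record, the absolute model-observation misfit before assimilation
#' minus the absolute misfit after: positive values mean the assimilation
#' decreased the misfit. Summarized by mean, median, and histogram counts,
#' overall and per observed quantity.
#'
#' @param spec the [cost_spec()] binding the observations.
#' @param prior_trajectory,posterior_trajectory n x (window+1) state
#'   matrices spanning all observation times.
#' @param breaks histogram break specification (passed to [hist()]).
#' @return List of class `"improvement_metric"`: `records` (per-observation
#'   table with an `improvement` column), `summary` (mean/median overall and
#'   by quantity), `histogram` (counts and breaks).
#' @export
improvement_metric <- function(spec, prior_trajectory, posterior_trajectory,
                               breaks = 11) {
  if (ncol(prior_trajectory) < spec$window + 1L || ncol(posterior_trajectory) < spec$window + 1L)
    stop("improvement_metric: trajectories do not span the observation window", call. = FALSE)
  prior <- fitted_obs(spec, prior_trajectory)
  post <- fitted_obs(spec, posterior_trajectory)
  imp <- abs(spec$obs$value - prior) - abs(spec$obs$value - post)
  rec <- cbind(spec$obs, prior = prior, posterior = post, improvement = imp)
  h <- graphics::hist(imp, breaks = breaks, plot = FALSE)
  by_q <- tapply(imp, spec$obs$quantity, mean)
  structure(list(records = rec,
                 summary = list(mean = mean(imp), median = stats::median(imp),
                                mean_by_quantity = by_q),
                 histogram = list(counts = h$counts, breaks = h$breaks)),
            class = "improvement_metric")
}

#' @export
print.improvement_metric <- function(x, ...) {
  cat("Model improvement at observation locations (positive = misfit decreased)\n")
  cat(sprintf("  mean %.4g, median %.4g over %d records\n",
              x$summary$mean, x$summary$median, nrow(x$records)))
  for (q in names(x$summary$mean_by_quantity))
    cat(sprintf("  %-12s mean improvement %.4g\n", q, x$summary$mean_by_quantity[[q]]))
  invisible(x)
}

#' Run a full identical-twin assimilation experiment
#'
#' Builds a synthetic truth by perturbing the background initial condition,
#' integrates it over the window, generates the two synthetic observation
#' streams, assimilates them with the incremental 4D-Var defaults, and
#' evaluates the improvement metric and initial-condition recovery.
#'
#' @param twin a [twin_config()].
#' @param params [nemuro_params()].
#' @param grid [column_grid()].
#' @param config a [minimizer_config()].
#' @param window assimilation window in model steps (default 96 steps of the
#'   default 3600 s grid step: a 4-day cycle).
#' @param surface_irradiance surface forcing, W m^-2.
#' @param sigma_b_frac diagonal background error std as a fraction of the
#'   per-variable background column mean.
#' @param background background initial state; default
#'   [nemuro_default_state()].
#' @return A list of class `"twin_report"`: the assimilation result, the
#'   improvement metric, truth/background/analysis initial states, recovery
#'   RMS before and after, and the observation set.
#' @export
run_twin_experiment <- function(twin = twin_config(), params = nemuro_params(),
                                grid = column_grid(), config = minimizer_config(),
                                window = 96, surface_irradiance = 150,
                                sigma_b_frac = 0.3, background = NULL) {
  model <- nemuro_model(params, grid, surface_irradiance)
  index <- model$index
  if (is.null(background)) background <- nemuro_default_state(grid)
  stopifnot(length(background) == index$n)
  truth0 <- local_seed(twin$seed,
    background * exp(twin$perturb_scale * stats::rnorm(index$n)))
  truth_traj <- run_trajectory(model, truth0, window)
  obs_cfg <- twin
  obs_cfg$seed <- twin$seed + 1L       # separate stream for noise and mask
  obs <- generate_observations(truth_traj, obs_cfg, params, index)
  per_var_mean <- vapply(index$variables,
                         function(v) mean(background[flat_index(index, v)]),
                         numeric(1))
  sigma_b <- pmax(sigma_b_frac * per_var_mean, 1e-3)
  spec <- cost_spec(background, sigma_b, obs, window, params, index)
  fit <- outer_loop(spec, model, config)
  prior_traj <- run_trajectory(model, background, window)
  post_traj <- run_trajectory(model, fit$analysis, window)
  imp <- improvement_metric(spec, prior_traj, post_traj)
  rms <- function(a, b) sqrt(mean((a - b)^2))
  structure(list(fit = fit, improvement = imp, observations = obs,
                 background = background, truth0 = truth0,
                 analysis = fit$analysis,
                 recovery_rms = c(before = rms(background, truth0),
                                  after = rms(fit$analysis, truth0)),
                 cost = c(initial = fit$cost_outer[1],
                          final = fit$cost_outer[length(fit$cost_outer)]),
                 window = window, twin = twin),
            class = "twin_report")
}

#' @export
print.twin_report <- function(x, ...) {
  cat(sprintf("Twin experiment: %d-step window, %d observations\n",
              x$window, nrow(x$observations)))
  cat(sprintf("  nonlinear cost %.6g -> %.6g\n", x$cost["initial"], x$cost["final"]))
  cat(sprintf("  initial-condition RMS error %.4g -> %.4g\n",
              x$recovery_rms["before"], x$recovery_rms["after"]))
  print(x$improvement)
  invisible(x)
}
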