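#' Specify the strong-constraint 4D-Var cost function
#'
#' The cost of an initial-condition increment \eqn{\delta x} is
#' \deqn{J(\delta x) = \tfrac12 \delta x^T B^{-1} \delta x + \tfrac12
#' \sum_k (H_k(x_k) - y_k)^T R^{-1} (H_k(x_k) - y_k),}
#' with the trajectory \eqn{x_k} launched from `background + increment`
#' (strong constraint: the model is treated as error-free). B and R are
#' diagonal: `sigma_b` holds background error standard deviations, the
#' observation table holds per-record error standard deviations. Observed
#' quantities are either state variables (sampled directly) or
#' `"chlorophyll"` (the fixed-ratio diagnostic `chl2n * (PS + PL)`).
#' Observation times are snapped to the nearest model step, ties rounding
#' down.
#'
#' @param background background initial state (flat vector).
#' @param sigma_b background error std: scalar, per-variable named vector
#'   (length 11, recycled over cells), or full-length vector. Must be
#'   strictly positive.
#' @param observations data frame with columns `time` (model steps, may be
#'   fractional), `cell`, `quantity` (variable name or `"chlorophyll"`),
#'   `value`, `sigma`.
#' @param window assimilation window length in model steps (>= 1).
#' @param params [nemuro_params()] (supplies the chlorophyll conversion).
#' @param index the model's [state_index()].
#' @return An object of class `"cost_spec"`.
#' @export
cost_spec <- function(background, sigma_b, observations, window, params, index) {
  n <- index$n
  stopifnot(length(background) == n, window >= 1)
  nv <- index$n_vars
  if (length(sigma_b) == 1L) {
    sb <- rep(as.numeric(sigma_b), n)
  } else if (length(sigma_b) == nv) {
    if (!is.null(names(sigma_b))) sigma_b <- sigma_b[index$variables]
    sb <- rep(as.numeric(sigma_b), index$n_cells)
  } else if (length(sigma_b) == n) {
    sb <- as.numeric(sigma_b)
  } else {
    stop("cost_spec: sigma_b must have length 1, n_variables, or n", call. = FALSE)
  }
  if (any(!is.finite(sb) | sb <= 0))
    stop("cost_spec: background error stds must be strictly positive", call. = FALSE)
  obs <- as.data.frame(observations)
  req <- c("time", "cell", "quantity", "value", "sigma")
  if (!all(req %in% names(obs)))
    stop(sprintf("cost_spec: observations need columns %s", paste(req, collapse = ", ")), call. = FALSE)
  if (nrow(obs) && any(obs$sigma <= 0))
    stop("cost_spec: observation error stds must be strictly positive", call. = FALSE)
  stime <- as.integer(ceiling(obs$time - 0.5))   # nearest step, ties down
  if (nrow(obs) && (any(stime < 0) || any(stime > window)))
    stop(sprintf("cost_spec: observation at time %g lies outside the %d-step window",
                 obs$time[which(stime < 0 | stime > window)[1L]], window), call. = FALSE)
  if (nrow(obs) && any(obs$cell < 1 | obs$cell > index$n_cells))
    stop("cost_spec: observation cell index out of range", call. = FALSE)
  is_chl <- obs$quantity == "chlorophyll"
  if (nrow(obs) && !all(is_chl | obs$quantity %in% index$variables))
    stop(sprintf("cost_spec: unknown observed quantity '%s'",
                 setdiff(obs$quantity, c(index$variables, "chlorophyll"))[1L]), call. = FALSE)
  key <- paste(stime, obs$cell, obs$quantity)
  if (anyDuplicated(key))
    stop("cost_spec: duplicate (time, cell, quantity) observation records", call. = FALSE)
  pos_direct <- integer(nrow(obs))
  pos_ps <- integer(nrow(obs)); pos_pl <- integer(nrow(obs))
  for (r in seq_len(nrow(obs))) {
    if (is_chl[r]) {
      pos_ps[r] <- flat_index(index, "PS", obs$cell[r])
      pos_pl[r] <- flat_index(index, "PL", obs$cell[r])
    } else {
      pos_direct[r] <- flat_index(index, obs$quantity[r], obs$cell[r])
    }
  }
  structure(list(background = as.numeric(background), sigma_b = sb,
                 obs = obs, stime = stime, is_chl = is_chl,
                 pos_direct = pos_direct, pos_ps = pos_ps, pos_pl = pos_pl,
                 chl2n = params$chl2n, window = as.integer(window),
                 index = index, n = n),
            class = "cost_spec")
}

# model-equivalent values for observation rows, given the state at their time
obs_predict <- function(spec, state, rows) {
  out <- numeric(length(rows))
  chl <- spec$is_chl[rows]
  if (any(!chl)) out[!chl] <- state[spec$pos_direct[rows[!chl]]]
  if (any(chl))
    out[chl] <- spec$chl2n * (state[spec$pos_ps[rows[chl]]] + state[spec$pos_pl[rows[chl]]])
  out
}

# H^T r: scatter weighted residuals back onto a state-sized vector
obs_adjoint <- function(spec, rows, r) {
  w <- numeric(spec$n)
  chl <- spec$is_chl[rows]
  if (any(!chl)) {
    p <- spec$pos_direct[rows[!chl]]
    w[p] <- w[p] + r[!chl]
  }
  if (any(chl)) {
    pps <- spec$pos_ps[rows[chl]]; ppl <- spec$pos_pl[rows[chl]]
    w[pps] <- w[pps] + spec$chl2n * r[chl]
    w[ppl] <- w[ppl] + spec$chl2n * r[chl]
  }
  w
}

# tangent of H applied to a perturbation state (H is linear: same gather)
obs_tlm <- function(spec, u, rows) obs_predict(spec, u, rows)

rows_by_time <- function(spec) {
  split(seq_len(nrow(spec$obs)), factor(spec$stime, levels = 0:spec$window))
}

#' Nonlinear 4D-Var cost and its adjoint gradient
#'
#' Runs the nonlinear trajectory from `background + increment`, accumulates
#' the background and observation misfit terms, and computes the exact
#' gradient with a single reverse-time adjoint sweep: observation-misfit
#' forcings \eqn{H^T R^{-1}(Hx - y)} are injected at their times and carried
#' back through the per-step adjoints (segmented when the model declares
#' segments).
#'
#' @param increment initial-condition increment (flat vector).
#' @param spec a [cost_spec()].
#' @param model a [model_function()] advancing one step.
#' @return List with `cost`, `gradient`, `cost_background`, `cost_obs`, and
#'   the `trajectory` matrix.
#' @export
cost_and_gradient <- function(increment, spec, model) {
  stopifnot(length(increment) == spec$n)
  traj <- run_trajectory(model, spec$background + increment, spec$window)
  segments <- !is.null(model$segments)
  rt <- rows_by_time(spec)
  jo <- 0
  w <- numeric(spec$n)
  for (t in spec$window:0) {
    rows <- rt[[as.character(t)]]
    if (length(rows)) {
      resid <- obs_predict(spec, traj[, t + 1L], rows) - spec$obs$value[rows]
      sg <- spec$obs$sigma[rows]
      jo <- jo + 0.5 * sum((resid / sg)^2)
      w <- w + obs_adjoint(spec, rows, resid / sg^2)
    }
    if (t > 0) {
      w <- if (segments) adjoint_segmented(model, traj[, t], w, check = FALSE)
           else adjoint_multidual(model, traj[, t], w)
    }
  }
  jb <- 0.5 * sum((increment / spec$sigma_b)^2)
  list(cost = jb + jo, gradient = increment / spec$sigma_b^2 + w,
       cost_background = jb, cost_obs = jo, trajectory = traj)
}

#' Minimizer configuration
#'
#' Defaults mirror a standard incremental configuration: 10 inner conjugate
#' gradient iterations per outer loop and 2 outer loops, with the
#' control-variable transform \eqn{v = B^{-1/2}\delta x} as preconditioner.
#'
#' @param n_outer outer loops (re-linearizations).
#' @param n_inner inner CG iterations per outer loop.
#' @param cg_tol relative-residual stopping tolerance, secondary to the
#'   `n_inner` cap.
#' @param precondition use the control-variable transform.
#' @return A list of class `"minimizer_config"`.
#' @export
minimizer_config <- function(n_outer = 2, n_inner = 10, cg_tol = 1e-10,
                             precondition = TRUE) {
  stopifnot(n_outer >= 1, n_inner >= 1, cg_tol > 0)
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 cg_tol = cg_tol, precondition = isTRUE(precondition)),
            class = "minimizer_config")
}

# TLM sweep: propagate an initial perturbation through the stored trajectory
# and sample it at the observation rows (per time)
tlm_obs_sweep <- function(model, spec, traj, u0, rt) {
  out <- numeric(nrow(spec$obs))
  u <- u0
  rows <- rt[["0"]]
  if (length(rows)) out[rows] <- obs_tlm(spec, u, rows)
  for (t in seq_len(spec$window)) {
    u <- evaluate_tlm(model, traj[, t], u)
    rows <- rt[[as.character(t)]]
    if (length(rows)) out[rows] <- obs_tlm(spec, u, rows)
  }
  out
}

# adjoint sweep: carry weighted observation-space residuals back to time 0
adj_obs_sweep <- function(model, spec, traj, r, rt) {
  segments <- !is.null(model$segments)
  w <- numeric(spec$n)
  for (t in spec$window:0) {
    rows <- rt[[as.character(t)]]
    if (length(rows)) w <- w + obs_adjoint(spec, rows, r[rows])
    if (t > 0) {
      w <- if (segments) adjoint_segmented(model, traj[, t], w, check = FALSE)
           else adjoint_multidual(model, traj[, t], w)
    }
  }
  w
}

#' Inner-loop quadratic minimization
#'
#' Conjugate-gradient minimization of the incremental (linearized) cost
#' about the supplied trajectory, with innovations held fixed: in control
#' space \eqn{v = B^{-1/2} \delta x} the Hessian is \eqn{I + B^{1/2} M'^T
#' H^T R^{-1} H M' B^{1/2}} (identity-plus-positive-semidefinite, so CG
#' applies). Each Hessian application costs one tangent-linear and one
#' adjoint sweep of the window. Stops after `n_inner` iterations or at the
#' relative-residual tolerance.
#'
#' @param spec a [cost_spec()].
#' @param model a [model_function()].
#' @param traj linearization trajectory (n x window+1 matrix) from the
#'   current outer guess.
#' @param v_outer control-space representation of the current total
#'   increment.
#' @param config a [minimizer_config()].
#' @return List with the updated control `v`, the increment `dx`, the
#'   quadratic `cost` per iteration (non-increasing), and sweep counts.
#' @export
inner_loop <- function(spec, model, traj, v_outer, config = minimizer_config()) {
  s <- if (config$precondition) spec$sigma_b else rep(1, spec$n)
  binv <- if (config$precondition) rep(1, spec$n) else 1 / spec$sigma_b^2
  rt <- rows_by_time(spec)
  sweeps <- 0L
  rsig2 <- spec$obs$sigma^2
  # innovations about the outer trajectory
  d <- numeric(nrow(spec$obs))
  for (t in 0:spec$window) {
    rows <- rt[[as.character(t)]]
    if (length(rows))
      d[rows] <- spec$obs$value[rows] - obs_predict(spec, traj[, t + 1L], rows)
  }
  A <- function(u) {
    sweeps <<- sweeps + 1L
    gu <- tlm_obs_sweep(model, spec, traj, s * u, rt)
    binv * u + s * adj_obs_sweep(model, spec, traj, gu / rsig2, rt)
  }
  b <- -binv * v_outer + s * adj_obs_sweep(model, spec, traj, d / rsig2, rt)
  const <- 0.5 * sum(binv * v_outer^2) + 0.5 * sum(d^2 / rsig2)
  x <- numeric(spec$n)
  ax <- numeric(spec$n)
  r <- b
  p <- r
  rs <- sum(r * r)
  rs0 <- rs
  costs <- const                      # quadratic cost at the starting point
  for (it in seq_len(config$n_inner)) {
    if (sqrt(rs / max(rs0, .Machine$double.xmin)) <= config$cg_tol) break
    Ap <- A(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0)
      stop("inner_loop: non-positive curvature encountered; the tangent linear and adjoint models are inconsistent - run dot_product_test", call. = FALSE)
    alpha <- rs / pAp
    x <- x + alpha * p
    ax <- ax + alpha * Ap
    costs <- c(costs, 0.5 * sum(x * ax) - sum(b * x) + const)
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  v <- v_outer + x
  list(v = v, dx = s * v, cost = costs, sweeps = sweeps)
}

#' Incremental strong-constraint 4D-Var outer loop
#'
#' Runs `n_outer` cycles of: nonlinear trajectory from the current guess,
#' fixed innovations, inner-loop quadratic minimization, guess update.
#'
#' @inheritParams inner_loop
#' @param config a [minimizer_config()].
#' @return An `assimilation_result`: the analysis `increment` and
#'   `analysis` initial state, nonlinear `cost_outer` per outer loop (plus
#'   the final analysis cost), the quadratic `cost_inner` trajectories, the
#'   per-observation table with prior/posterior equivalents and innovations,
#'   and evaluation counters.
#' @export
outer_loop <- function(spec, model, config = minimizer_config()) {
  v <- numeric(spec$n)
  dx <- numeric(spec$n)
  cost_outer <- numeric(0)
  cost_inner <- list()
  n_traj <- 0L; n_sweeps <- 0L
  prior_fit <- NULL
  for (o in seq_len(config$n_outer)) {
    cg <- cost_and_gradient(dx, spec, model)   # also yields the trajectory
    n_traj <- n_traj + 1L
    cost_outer <- c(cost_outer, cg$cost)
    if (o == 1L) prior_fit <- fitted_obs(spec, cg$trajectory)
    il <- inner_loop(spec, model, cg$trajectory, v, config)
    cost_inner[[o]] <- il$cost
    n_sweeps <- n_sweeps + il$sweeps
    v <- il$v
    dx <- il$dx
  }
  cg <- cost_and_gradient(dx, spec, model)
  n_traj <- n_traj + 1L
  cost_outer <- c(cost_outer, cg$cost)
  post_fit <- fitted_obs(spec, cg$trajectory)
  tab <- cbind(spec$obs,
               prior = prior_fit, posterior = post_fit,
               innovation_before = spec$obs$value - prior_fit,
               innovation_after = spec$obs$value - post_fit)
  structure(list(increment = dx, analysis = spec$background + dx,
                 cost_outer = cost_outer, cost_inner = cost_inner,
                 observations = tab,
                 counters = c(nonlinear_trajectories = n_traj,
                              hessian_sweeps = n_sweeps),
                 config = config),
            class = "assimilation_result")
}

fitted_obs <- function(spec, traj) {
  rt <- rows_by_time(spec)
  out <- numeric(nrow(spec$obs))
  for (t in 0:spec$window) {
    rows <- rt[[as.character(t)]]
    if (length(rows)) out[rows] <- obs_predict(spec, traj[, t + 1L], rows)
  }
  out
}

#' @export
print.assimilation_result <- function(x, ...) {
  cat("Incremental 4D-Var analysis\n")
  cat(sprintf("  outer loops: %d, inner iterations: %d\n",
              x$config$n_outer, x$config$n_inner))
  cat(sprintf("  nonlinear cost: %.6g -> %.6g\n",
              x$cost_outer[1], x$cost_outer[length(x$cost_outer)]))
  cat(sprintf("  observations: %d, |increment|: %.4g\n",
              nrow(x$observations), sqrt(sum(x$increment^2))))
  invisible(x)
}
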