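# shared small assimilation setup: 2-layer column, 12-step window
fourdvar_fixture <- function(window = 12, noise = 0, seed = 3,
                             perturb = 0.2, K = 2) {
  grid <- small_grid(K)
  p <- nemuro_params()
  model <- nemuro_model(p, grid)
  index <- model$index
  background <- nemuro_default_state(grid)
  truth0 <- withr::with_seed(seed, background * exp(perturb * rnorm(index$n)))
  truth_traj <- run_trajectory(model, truth0, window)
  cfg <- twin_config(noise_dense = noise, noise_chl = noise, mask_fraction = 0.25,
                     obs_every = 3, seed = seed)
  obs <- generate_observations(truth_traj, cfg, p, index)
  spec <- cost_spec(background, 0.3 * pmax(background, 0.05), obs, window, p, index)
  list(grid = grid, p = p, model = model, index = index, background = background,
       truth0 = truth0, truth_traj = truth_traj, obs = obs, spec = spec,
       window = window)
}

test_that("the cost function reduces to its background term without observations", {
  fx <- fourdvar_fixture()
  empty <- fx$obs[0, ]
  spec <- cost_spec(fx$background, 0.3 * pmax(fx$background, 0.05), empty,
                    fx$window, fx$p, fx$index)
  dx <- withr::with_seed(1, 0.01 * rnorm(fx$index$n))
  cg <- cost_and_gradient(dx, spec, fx$model)
  expect_equal(cg$cost, 0.5 * sum((dx / spec$sigma_b)^2), tolerance = 1e-12)
  expect_equal(cg$gradient, dx / spec$sigma_b^2, tolerance = 1e-12)
})

test_that("noise-free observations of the background trajectory give a zero-cost fixed point", {
  fx <- fourdvar_fixture()
  bg_traj <- run_trajectory(fx$model, fx$background, fx$window)
  cfg <- twin_config(noise_dense = 0, noise_chl = 0, mask_fraction = 0, obs_every = 3)
  obs <- generate_observations(bg_traj, cfg, fx$p, fx$index)
  spec <- cost_spec(fx$background, 0.3 * pmax(fx$background, 0.05), obs,
                    fx$window, fx$p, fx$index)
  cg <- cost_and_gradient(numeric(fx$index$n), spec, fx$model)
  expect_equal(cg$cost, 0, tolerance = 1e-20)
  expect_equal(max(abs(cg$gradient)), 0, tolerance = 1e-20)
  fit <- outer_loop(spec, fx$model, minimizer_config())
  expect_equal(max(abs(fit$increment)), 0, tolerance = 1e-10)
})

test_that("the adjoint gradient matches finite differences along random directions", {
  fx <- fourdvar_fixture()
  dx0 <- numeric(fx$index$n)
  cg <- cost_and_gradient(dx0, fx$spec, fx$model)
  for (s in 1:5) {
    d <- withr::with_seed(100 + s, rnorm(fx$index$n))
    d <- d / sqrt(sum(d^2))
    h <- 1e-5
    jp <- cost_and_gradient(dx0 + h * d, fx$spec, fx$model)$cost
    jm <- cost_and_gradient(dx0 - h * d, fx$spec, fx$model)$cost
    fd <- (jp - jm) / (2 * h)
    expect_lt(abs(fd - sum(cg$gradient * d)) / abs(fd), 1e-5)
  }
})

test_that("the 4D-Var gradient passes the Taylor remainder test at background and analysis", {
  fx <- fourdvar_fixture()
  Jfun <- function(dx) cost_and_gradient(dx, fx$spec, fx$model)$cost
  cg0 <- cost_and_gradient(numeric(fx$index$n), fx$spec, fx$model)
  tt0 <- taylor_test(Jfun, cg0$gradient, numeric(fx$index$n), seed = 1)
  expect_gte(attr(tt0, "slope"), 1.9)
  fit <- outer_loop(fx$spec, fx$model, minimizer_config())
  cga <- cost_and_gradient(fit$increment, fx$spec, fx$model)
  tta <- taylor_test(Jfun, cga$gradient, fit$increment, seed = 2)
  expect_gte(attr(tta, "slope"), 1.9)
})

test_that("the inner loop decreases the quadratic cost monotonically", {
  fx <- fourdvar_fixture(noise = 0.1)
  cg <- cost_and_gradient(numeric(fx$index$n), fx$spec, fx$model)
  il <- inner_loop(fx$spec, fx$model, cg$trajectory, numeric(fx$index$n),
                   minimizer_config(n_inner = 10))
  expect_true(all(diff(il$cost) <= 1e-10 * abs(il$cost[1])))
  expect_gt(length(il$cost), 3)
  # with and without the control-variable transform the same quadratic is
  # minimized: run both to (exact Krylov) convergence and compare the costs
  il2 <- inner_loop(fx$spec, fx$model, cg$trajectory, numeric(fx$index$n),
                    minimizer_config(n_inner = 40, precondition = FALSE))
  il3 <- inner_loop(fx$spec, fx$model, cg$trajectory, numeric(fx$index$n),
                    minimizer_config(n_inner = 40))
  expect_true(all(diff(il2$cost) <= 1e-10 * abs(il2$cost[1])))
  j2 <- il2$cost[length(il2$cost)]; j3 <- il3$cost[length(il3$cost)]
  expect_lt(abs(j2 - j3) / j3, 1e-3)
})

test_that("outer loops reduce the nonlinear cost and count their evaluations", {
  fx <- fourdvar_fixture()
  config <- minimizer_config(n_outer = 2, n_inner = 10)
  fit <- outer_loop(fx$spec, fx$model, config)
  expect_identical(config$n_outer, 2L)
  expect_identical(config$n_inner, 10L)
  nlc <- fit$cost_outer
  expect_lt(nlc[length(nlc)], nlc[1])
  expect_true(all(diff(nlc) <= 1e-8 * nlc[1]))
  # one trajectory per outer loop plus the final analysis trajectory
  expect_identical(unname(fit$counters["nonlinear_trajectories"]),
                   config$n_outer + 1L)
  # each CG iteration costs one tangent-linear plus one adjoint sweep
  expect_lte(unname(fit$counters["hessian_sweeps"]), config$n_outer * config$n_inner)
})

test_that("with weak background constraint and full initial-time observability the truth is recovered", {
  grid <- small_grid(1)
  p <- nemuro_params()
  model <- nemuro_model(p, grid)
  index <- model$index
  background <- nemuro_default_state(grid)
  truth0 <- withr::with_seed(8, background * exp(0.15 * rnorm(index$n)))
  # noise-free observations of every state variable at the initial time
  obs <- data.frame(time = 0, cell = 1, quantity = nemuro_variables(),
                    value = truth0, sigma = 0.01)
  rms_err <- sapply(c(1, 10, 100), function(bscale) {
    spec <- cost_spec(background, bscale * pmax(background, 0.05), obs, 4, p, index)
    fit <- outer_loop(spec, model, minimizer_config(n_outer = 2, n_inner = 15))
    sqrt(mean((fit$analysis - truth0)^2))
  })
  expect_true(all(diff(rms_err) <= 1e-12))   # recovery improves as B loosens
  expect_lt(rms_err[3] / sqrt(mean(truth0^2)), 0.01)
})

test_that("observation binding snaps times to steps and validates the records", {
  fx <- fourdvar_fixture()
  obs <- data.frame(time = c(2.4, 2.5, 2.6), cell = c(1, 2, 1), quantity = "NO3",
                    value = 8, sigma = 0.1)
  spec <- cost_spec(fx$background, 1, obs, fx$window, fx$p, fx$index)
  expect_identical(spec$stime, c(2L, 2L, 3L))          # ties round down
  bad_time <- data.frame(time = 40, cell = 1, quantity = "NO3", value = 8, sigma = 0.1)
  expect_error(cost_spec(fx$background, 1, bad_time, 12, fx$p, fx$index), "window")
  bad_q <- data.frame(time = 1, cell = 1, quantity = "temperature", value = 8, sigma = 0.1)
  expect_error(cost_spec(fx$background, 1, bad_q, 12, fx$p, fx$index), "quantity")
  dup <- data.frame(time = c(1, 1), cell = 1, quantity = "NO3", value = 8, sigma = 0.1)
  expect_error(cost_spec(fx$background, 1, dup, 12, fx$p, fx$index), "duplicate")
  zero_sig <- data.frame(time = 1, cell = 1, quantity = "NO3", value = 8, sigma = 0)
  expect_error(cost_spec(fx$background, 1, zero_sig, 12, fx$p, fx$index), "strictly positive")
})
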