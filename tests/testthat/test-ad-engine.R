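test_that("tangent linear evaluation reproduces Jacobian-vector products", {
  A <- matrix(c(2, -1, 0.5, 3, 0, 1, -2, 1, 4), 3, 3)
  lm_ <- linear_model(A)
  x <- c(1, 2, 3); u <- c(0.5, -1, 2)
  expect_equal(as.numeric(evaluate_tlm(lm_, x, u)), drop(A %*% u), tolerance = 1e-14)
  # zero seed, and the nonlinear value rides along unchanged
  res <- evaluate_tlm(lm_, x, numeric(3))
  expect_identical(as.numeric(res), numeric(3))
  expect_identical(attr(res, "value"), drop(A %*% x))

  qm <- quad_model(2)
  got <- evaluate_tlm(qm, c(3, 0), c(1, 1))
  expect_equal(as.numeric(got), c(8, -4))     # f'(x) = 4 (x - 1)
})

test_that("real parts of dual evaluations are bitwise equal to plain evaluations", {
  sm <- smooth_model()
  x <- seq(0.1, 0.8, length.out = sm$n)
  plain <- sm$raw_fn(x)
  res <- evaluate_tlm(sm, x, rnorm(sm$n))
  expect_identical(attr(res, "value"), plain)
  md <- sm$raw_fn(dualvar:::new_dual(x, diag(sm$n)))
  expect_identical(md$real, plain)
})

test_that("tangent linear evaluation is linear in the perturbation", {
  sm <- smooth_model()
  x <- seq(-0.5, 0.9, length.out = sm$n)
  withr::with_seed(3, {
    u <- rnorm(sm$n); v <- rnorm(sm$n)
  })
  lhs <- evaluate_tlm(sm, x, 2.5 * u - 1.25 * v)
  rhs <- 2.5 * evaluate_tlm(sm, x, u) - 1.25 * evaluate_tlm(sm, x, v)
  expect_lt(rel_diff(as.numeric(lhs), as.numeric(rhs)), 1e-12)
})

test_that("the three adjoint variants agree and match the transposed finite-difference Jacobian", {
  sm <- smooth_model()
  x <- seq(0.2, 1.1, length.out = sm$n)
  w <- withr::with_seed(5, rnorm(sm$n))
  bf <- adjoint_bruteforce(sm, x, w)
  md <- adjoint_multidual(sm, x, w)
  expect_identical(bf, md)                    # same arithmetic, batched
  expect_equal(adjoint_multidual(sm, x, w, chunk = 3), bf, tolerance = 1e-14)
  fd <- drop(crossprod(fd_jacobian(sm, x), w))
  expect_lt(rel_diff(bf, fd), 1e-6)
  # linear map: adjoint is the plain transpose
  A <- matrix(rnorm(16), 4, 4)
  lm_ <- linear_model(A)
  w4 <- c(1, -2, 3, 0.5)
  expect_equal(adjoint_multidual(lm_, rep(1, 4), w4), drop(crossprod(A, w4)),
               tolerance = 1e-13)
  expect_identical(adjoint_bruteforce(sm, x, numeric(sm$n)), numeric(sm$n))
})

test_that("adjoint call counts follow the column-by-column construction", {
  sm <- smooth_model()
  x <- rep(0.5, sm$n); w <- rep(1, sm$n)
  reset_counter(sm)
  adjoint_bruteforce(sm, x, w)
  expect_identical(eval_count(sm), sm$n)      # one evaluation per unit vector
  reset_counter(sm)
  adjoint_multidual(sm, x, w)
  expect_identical(eval_count(sm), 1L)        # one call, n independent dual parts
  reset_counter(sm)
  evaluate_tlm(sm, x, w)
  expect_identical(eval_count(sm), 1L)
})

test_that("the Jacobian materializes column-by-column under a size cap", {
  idm <- model_function(function(x) x + 0, toy_index(1, 4))
  expect_equal(unclass(build_jacobian(idm, rep(1, 4)))[, ], diag(4))
  qm <- quad_model(2)
  J <- build_jacobian(qm, c(3, 0))
  expect_equal(unclass(J)[, ], diag(c(8, -4)))
  sm <- smooth_model()
  x <- seq(0.1, 1, length.out = sm$n)
  expect_lt(rel_diff(unclass(build_jacobian(sm, x))[, ], fd_jacobian(sm, x)), 1e-6)
  expect_error(build_jacobian(sm, x, cap = 4), "cap")
})

test_that("segmented adjoints of composed maps match the monolithic brute force", {
  # two sequential segments over a 2-cell, 3-variable state: a pointwise
  # reaction reading two variables and a global linear mixing
  index <- state_index(2, c("a", "b", "c"))
  mix <- withr::with_seed(11, {
    M <- diag(6) + 0.05 * matrix(rnorm(36), 6)
    M
  })
  react <- function(x) {
    ia <- flat_index(index, "a"); ib <- flat_index(index, "b"); ic <- flat_index(index, "c")
    y <- x
    y[ib] <- x[ib] + 0.1 * x[ia]^2
    y[ic] <- x[ic] + 0.2 * exp(-x[ia]) * x[ib]
    y
  }
  segs <- list(
    segment_spec("react", reads = c("a", "b"), writes = c("b", "c"),
                 locality = "pointwise", fn = react),
    segment_spec("mix", reads = c("a", "b", "c"), writes = c("a", "b", "c"),
                 locality = "global",
                 fn = function(x) dualvar:::apply_linear(function(v) drop(mix %*% v), x))
  )
  model <- model_function(function(x) segs[[2]]$fn(segs[[1]]$fn(x)), index, segments = segs)
  x <- withr::with_seed(2, runif(6, 0.5, 1.5))
  w <- withr::with_seed(3, rnorm(6))
  expect_lt(rel_diff(adjoint_segmented(model, x, w), adjoint_bruteforce(model, x, w)), 1e-12)
  reset_counter(model)
  adjoint_segmented(model, x, w)
  expect_identical(unname(seed_dims(model)["react"]), 2L)  # reads, not n = 6
  expect_true(check_footprints(model, x))

  # an under-declared read set is caught by the probe
  bad <- segment_spec("react", reads = "a", writes = c("b", "c"),
                      locality = "pointwise", fn = react)
  model_bad <- model_function(model$raw_fn, index, segments = list(bad, segs[[2]]))
  expect_error(check_footprints(model_bad, x), "read set")

  # an incomplete segment list is caught against the monolithic evaluation
  model_inc <- model_function(model$raw_fn, index, segments = segs[1])
  expect_error(adjoint_segmented(model_inc, x, w), "incomplete")
})

test_that("the dot-product identity holds for consistent pairs and flags corrupted ones", {
  A <- matrix(c(1, 2, 0, -1), 2, 2)
  lm_ <- linear_model(A)
  dp <- dot_product_test(lm_, c(1, 1), trials = 5, seed = 1)
  expect_true(attr(dp, "pass"))
  expect_lt(max(dp$discrepancy), 1e-13)

  sm <- smooth_model()
  dp2 <- dot_product_test(sm, seq(0.2, 1, length.out = sm$n), trials = 20, seed = 0)
  expect_true(attr(dp2, "pass"))

  # corrupt the multi-dual path only (sign flip in one propagated column):
  # the tangent linear and adjoint sides then disagree
  corrupt <- model_function(function(x) {
    y <- sm$raw_fn(x)
    if (is_dual(y) && ncol(y$dual) > 1) y$dual[1, 1] <- -y$dual[1, 1]
    y
  }, sm$index)
  dp3 <- dot_product_test(corrupt, seq(0.2, 1, length.out = sm$n),
                          trials = 5, seed = 0, adjoint = "multidual")
  expect_false(attr(dp3, "pass"))
})

test_that("the Taylor remainder test separates exact from perturbed gradients", {
  # quadratic J: remainder is exactly quadratic in h
  Q <- diag(c(1, 2, 3))
  J <- function(x) 0.5 * sum(x * drop(Q %*% x))
  x <- c(1, -1, 2)
  g <- drop(Q %*% x)
  tt <- taylor_test(J, g, x, seed = 4)
  expect_true(attr(tt, "pass"))
  expect_gt(attr(tt, "slope"), 1.95)
  # a 1% gradient error floors the convergence at first order
  bad <- taylor_test(J, 1.01 * g, x, seed = 4)
  expect_false(attr(bad, "pass"))
  expect_lt(attr(bad, "slope"), 1.5)
  expect_error(taylor_test(J, g, x, direction = numeric(3)), "nonzero")
})
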