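# Small differentiation targets used across the tests. They use the model
# variable set so the flat indexing matches the engine's expectations.

toy_index <- function(n_cells = 1, n_vars = 5) {
  state_index(n_cells, paste0("v", seq_len(n_vars)))
}

# linear map x -> A x
linear_model <- function(A, index = toy_index(1, nrow(A))) {
  model_function(function(x) {
    if (is_dual(x)) new_dual(drop(A %*% x$real), A %*% x$dual)
    else drop(A %*% x)
  }, index)
}

# elementwise f(x) = 2 (x - 1)^2 + 3, the classic scalar example, with
# derivative f'(x) = 4 (x - 1)
quad_model <- function(n = 2) {
  model_function(function(x) 2 * (x - 1)^2 + 3, toy_index(1, n))
}

# smooth nonlinear map mixing the supported elementary functions
smooth_model <- function(n = 8, seed = 42) {
  A <- dualvar:::local_seed(seed, matrix(rnorm(n * n, sd = 0.3), n, n))
  model_function(function(x) {
    y <- x
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + A[i, j] * x[j]
      y[i] <- tanh(acc) + 0.1 * exp(-(x[i] - 1)^2) + 0.05 * sin(x[i])
    }
    y
  }, toy_index(1, n))
}

# dense central-difference Jacobian oracle, step 1e-6 * (1 + |x_i|)
fd_jacobian <- function(model, x) {
  n <- model$n
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- 1e-6 * (1 + abs(x[i]))
    ep <- x; ep[i] <- ep[i] + h
    em <- x; em[i] <- em[i] - h
    J[, i] <- (model$raw_fn(ep) - model$raw_fn(em)) / (2 * h)
  }
  J
}

small_grid <- function(K = 2, dt = 3600) column_grid(n_layers = K, dz = 5, kv = 1e-4, dt = dt)

# random strictly positive column states for property-style tests
random_states <- function(grid, k = 3, seed = 7) {
  base <- nemuro_default_state(grid)
  dualvar:::local_seed(seed, lapply(seq_len(k), function(i)
    base * exp(0.3 * rnorm(length(base)))))
}

rel_diff <- function(a, b) max(abs(a - b)) / max(max(abs(a)), max(abs(b)), .Machine$double.xmin)
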