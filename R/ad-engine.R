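#' Flat state indexing over (cell, variable)
#'
#' The model state is a flat numeric vector in cell-major order: all
#' variables of cell 1 are contiguous, then cell 2, and so on. For a single
#' water column, cells are vertical layers with the surface at cell 1.
#'
#' @param n_cells number of grid cells (layers).
#' @param variables character vector of variable names.
#' @return An object of class `"state_index"`.
#' @export
state_index <- function(n_cells, variables) {
  stopifnot(n_cells >= 1, length(variables) >= 1, !anyDuplicated(variables))
  structure(list(n_cells = as.integer(n_cells),
                 variables = as.character(variables),
                 n_vars = length(variables),
                 n = as.integer(n_cells) * length(variables)),
            class = "state_index")
}

#' @rdname state_index
#' @param index a `state_index`.
#' @param cells integer cell indices (default all).
#' @param vars variable names (default all).
#' @return `flat_index()`: integer positions of the requested
#'   (cell, variable) combinations, ordered cell-major.
#' @export
flat_index <- function(index, vars = index$variables, cells = seq_len(index$n_cells)) {
  iv <- match(vars, index$variables)
  if (anyNA(iv)) stop(sprintf("unknown variable(s): %s",
                              paste(vars[is.na(iv)], collapse = ", ")), call. = FALSE)
  if (any(cells < 1L | cells > index$n_cells))
    stop("cell index out of range", call. = FALSE)
  as.integer(outer(iv, (cells - 1L) * index$n_vars, `+`))
}

#' Declare a biogeochemical process segment
#'
#' A segment is one state-to-state map in a sequentially composed model step.
#' Its declared `reads`/`writes` footprint and locality class drive the
#' reduced-cost adjoint: for a `"pointwise"` segment the outputs in a cell
#' depend only on inputs in the same cell, so one multi-dual evaluation with
#' seed dimension `length(reads)` (not the full state size) recovers every
#' per-cell Jacobian block at once. Footprints may over-declare dependencies
#' (correct but slower), never under-declare; see [check_footprints()].
#'
#' @param name segment label.
#' @param reads,writes variable names the segment depends on / updates.
#'   `writes` must be a subset of `reads` whenever an updated variable
#'   depends on its own previous value (the usual case).
#' @param locality one of `"pointwise"`, `"vertical-column"`, `"global"`.
#' @param fn the segment evaluator: a full-state map `function(x)` written
#'   with overloaded arithmetic so it accepts plain or dual states.
#' @param tlm_fn,adjoint_fn optional hand-coded tangent linear and adjoint,
#'   `function(x_in, v)`, linearized about the segment INPUT state. When
#'   supplied they are used instead of the dual-number machinery (the role
#'   played by pre-existing adjoint code for transport, sinking, and light
#'   attenuation in host ocean models).
#' @return An object of class `"segment_spec"`.
#' @export
segment_spec <- function(name, reads, writes, locality = c("pointwise", "vertical-column", "global"),
                         fn, tlm_fn = NULL, adjoint_fn = NULL) {
  locality <- match.arg(locality)
  structure(list(name = name, reads = reads, writes = writes,
                 locality = locality, fn = fn,
                 tlm_fn = tlm_fn, adjoint_fn = adjoint_fn),
            class = "segment_spec")
}

#' Wrap a nonlinear model evaluator for differentiation
#'
#' The evaluator maps a state vector of length `index$n` to a vector of the
#' same length, and must be written with overloaded operations so that the
#' same code runs on plain numeric, dual, and multi-dual states, with the
#' real part of any dual evaluation bitwise equal to the plain evaluation.
#' Every call through the wrapper is counted (see [eval_count()]), which
#' makes the cost structure of the adjoint variants measurable.
#'
#' @param fn the evaluator.
#' @param index a [state_index()].
#' @param segments optional list of [segment_spec()] entries whose sequential
#'   composition equals `fn`; enables [adjoint_segmented()].
#' @param name model label.
#' @return An object of class `"model_function"`.
#' @export
model_function <- function(fn, index, segments = NULL, name = "model") {
  counter <- new.env(parent = emptyenv())
  counter$evals <- 0L
  counter$segment_seed_dims <- list()
  counted <- function(x) {
    counter$evals <- counter$evals + 1L
    fn(x)
  }
  structure(list(fn = counted, raw_fn = fn, index = index, n = index$n,
                 segments = segments, name = name, counter = counter),
            class = "model_function")
}

#' @rdname model_function
#' @param model a `model_function`.
#' @export
reset_counter <- function(model) {
  model$counter$evals <- 0L
  model$counter$segment_seed_dims <- list()
  invisible(model)
}

#' @rdname model_function
#' @return `eval_count()`: number of evaluator invocations since the last
#'   reset; `seed_dims()`: named integer vector of the largest multi-dual
#'   seed dimension used per segment by [adjoint_segmented()].
#' @export
eval_count <- function(model) model$counter$evals

#' @rdname model_function
#' @export
seed_dims <- function(model) {
  sd <- model$counter$segment_seed_dims
  if (!length(sd)) return(integer(0))
  vapply(sd, max, integer(1))
}

record_seed_dim <- function(model, seg_name, s) {
  cur <- model$counter$segment_seed_dims
  cur[[seg_name]] <- c(cur[[seg_name]], as.integer(s))
  model$counter$segment_seed_dims <- cur
  invisible(NULL)
}

#' Nonlinear, tangent linear, and adjoint model evaluations
#'
#' `evaluate_model()` runs the plain nonlinear model. `evaluate_tlm()`
#' computes the tangent-linear product \eqn{M(x_{NL}) \cdot x_{TL}} as the
#' dual part of a SINGLE nonlinear evaluation at \eqn{x_{NL} + x_{TL}
#' \epsilon}; the real part of that evaluation (returned in attribute
#' `"value"`) is the nonlinear solution itself, unchanged.
#'
#' The adjoint product \eqn{M(x_{NL})^T \cdot x_{AD}} cannot be read off one
#' single-part dual evaluation; it is reconstructed column-by-column:
#' `adjoint_bruteforce()` makes `n` tangent-linear evaluations seeded with
#' the unit vectors and accumulates \eqn{\sum_i e_i (M e_i)^T x_{AD}};
#' `adjoint_multidual()` replaces the `n` calls by a single evaluation on a
#' multi-dual state with `n` independent dual parts (the repeated real-part
#' computation is shared), giving floating-point identical coefficients;
#' `adjoint_segmented()` further shrinks the effective seed dimension using
#' the declared process segments (see [segment_spec()]).
#'
#' @param model a [model_function()].
#' @param x state vector (length `model$n`).
#' @param x_nl linearization state.
#' @param x_tl perturbation (tangent) vector.
#' @param x_ad adjoint seed vector.
#' @return `evaluate_model()`: the output state. `evaluate_tlm()`: the
#'   tangent-linear product, with the nonlinear output as attribute
#'   `"value"`. The adjoint variants: the adjoint product vector.
#' @export
evaluate_model <- function(model, x) {
  stopifnot(length(x) == model$n)
  model$fn(as.numeric(x))
}

#' @rdname evaluate_model
#' @export
evaluate_tlm <- function(model, x_nl, x_tl) {
  stopifnot(length(x_nl) == model$n, length(x_tl) == model$n)
  out <- model$fn(new_dual(as.numeric(x_nl), matrix(as.numeric(x_tl))))
  structure(drop(out$dual), value = out$real)
}

#' @rdname evaluate_model
#' @export
adjoint_bruteforce <- function(model, x_nl, x_ad) {
  stopifnot(length(x_nl) == model$n, length(x_ad) == model$n)
  n <- model$n
  x_nl <- as.numeric(x_nl); x_ad <- as.numeric(x_ad)
  res <- numeric(n)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- 1
    col_i <- model$fn(new_dual(x_nl, matrix(ei)))$dual
    res[i] <- sum(col_i * x_ad)
  }
  res
}

#' @rdname evaluate_model
#' @param chunk seeds per multi-dual call; default the full state size, i.e.
#'   exactly one evaluator call. Smaller chunks trade calls for memory.
#' @export
adjoint_multidual <- function(model, x_nl, x_ad, chunk = NULL) {
  stopifnot(length(x_nl) == model$n, length(x_ad) == model$n)
  n <- model$n
  x_nl <- as.numeric(x_nl); x_ad <- as.numeric(x_ad)
  if (is.null(chunk)) chunk <- n
  stopifnot(chunk >= 1)
  res <- numeric(n)
  done <- 0L
  while (done < n) {
    cols <- (done + 1L):min(done + chunk, n)
    E <- matrix(0, n, length(cols))
    E[cbind(cols, seq_along(cols))] <- 1
    J <- model$fn(new_dual(x_nl, E))$dual          # columns of M(x_nl)
    # accumulate sum(J[, k] * x_ad) in the same order as adjoint_bruteforce
    res[cols] <- vapply(seq_along(cols), function(k) sum(J[, k] * x_ad), numeric(1))
    done <- done + length(cols)
  }
  res
}

#' @rdname evaluate_model
#' @param check verify on entry that the declared segments compose to the
#'   monolithic model at `x_nl` (one extra nonlinear evaluation).
#' @export
adjoint_segmented <- function(model, x_nl, x_ad, check = TRUE) {
  segs <- model$segments
  if (is.null(segs) || !length(segs))
    stop("adjoint_segmented: the model declares no segments", call. = FALSE)
  stopifnot(length(x_nl) == model$n, length(x_ad) == model$n)
  x_nl <- as.numeric(x_nl); x_ad <- as.numeric(x_ad)
  k <- length(segs)
  inputs <- vector("list", k)        # per-segment linearization states
  x <- x_nl
  for (j in seq_len(k)) {
    inputs[[j]] <- x
    x <- segs[[j]]$fn(x)
  }
  if (check) {
    mono <- model$fn(x_nl)
    if (max(abs(x - mono)) > 1e-10 * max(1, max(abs(mono))))
      stop("adjoint_segmented: segment composition disagrees with the monolithic model; the segment list is incomplete or out of order", call. = FALSE)
  }
  w <- x_ad
  for (j in rev(seq_len(k))) w <- segment_adjoint(model, segs[[j]], inputs[[j]], w)
  w
}

# Adjoint of a single segment about its input state.
# Segments are identity-plus-transfer maps: y_i = x_i outside the write set
# and y_i = x_i + u_i(x[reads]) inside it (a written variable that feeds
# back into its own transfer must be in the read set). The Jacobian is
# I + U with U supported on (writes x reads), so J^T w = w + U^T w[writes]
# scattered onto the reads. U is the dual part of a multi-dual evaluation
# seeded on the reads, minus the seed matrix itself (which carries the
# identity of the seeded directions).
segment_adjoint <- function(model, seg, x_in, w) {
  if (!is.null(seg$adjoint_fn)) return(seg$adjoint_fn(x_in, w))
  index <- model$index
  n <- index$n
  if (seg$locality == "pointwise") {
    s <- length(seg$reads)
    record_seed_dim(model, seg$name, s)
    E <- matrix(0, n, s)
    for (j in seq_len(s)) E[flat_index(index, seg$reads[j]), j] <- 1
    D <- seg$fn(new_dual(x_in, E))$dual - E
    out <- w
    for (c in seq_len(index$n_cells)) {
      wp <- flat_index(index, seg$writes, c)
      rp <- flat_index(index, seg$reads, c)
      out[rp] <- out[rp] + drop(crossprod(D[wp, , drop = FALSE], w[wp]))
    }
    out
  } else {
    rp <- flat_index(index, seg$reads)
    wp <- flat_index(index, seg$writes)
    s <- length(rp)
    record_seed_dim(model, seg$name, s)
    E <- matrix(0, n, s)
    E[cbind(rp, seq_len(s))] <- 1
    D <- seg$fn(new_dual(x_in, E))$dual - E
    out <- w
    out[rp] <- out[rp] + drop(crossprod(D[wp, , drop = FALSE], w[wp]))
    out
  }
}

#' Tangent linear sweep through declared segments
#'
#' Applies the hand-coded segment TLMs where declared and single-dual
#' evaluations elsewhere, in forward segment order. Equivalent to
#' [evaluate_tlm()] on the composed model; used to cross-validate hand-coded
#' linearizations against the dual-number path.
#' @inheritParams adjoint_segmented
#' @param x_tl perturbation vector.
#' @export
tlm_segmented <- function(model, x_nl, x_tl) {
  segs <- model$segments
  if (is.null(segs) || !length(segs))
    stop("tlm_segmented: the model declares no segments", call. = FALSE)
  x <- as.numeric(x_nl)
  u <- as.numeric(x_tl)
  for (seg in segs) {
    if (!is.null(seg$tlm_fn)) {
      u <- seg$tlm_fn(x, u)
      x <- seg$fn(x)
    } else {
      out <- seg$fn(new_dual(x, matrix(u)))
      u <- drop(out$dual)
      x <- out$real
    }
  }
  u
}

#' Materialize the tangent linear (Jacobian) matrix
#'
#' Column i is `evaluate_tlm(model, x_nl, e_i)`; all columns are obtained
#' from one multi-dual evaluation with the n unit seeds. Guarded by a size
#' cap because dense storage defeats the purpose at realistic state sizes.
#'
#' @inheritParams evaluate_model
#' @param cap refuse to materialize when `model$n` exceeds this.
#' @return An n-by-n matrix of class `"tlm_matrix"` (rows: outputs, columns:
#'   inputs), with the `state_index` attached as attribute `"index"`.
#' @export
build_jacobian <- function(model, x_nl, cap = 5000) {
  n <- model$n
  if (n > cap)
    stop(sprintf("build_jacobian: state size %d exceeds cap %d; use adjoint_segmented or matrix-free products instead", n, cap), call. = FALSE)
  stopifnot(length(x_nl) == n)
  E <- diag(n)
  J <- model$fn(new_dual(as.numeric(x_nl), E))$dual
  structure(J, class = c("tlm_matrix", class(J)), index = model$index)
}

#' Footprint probe check
#'
#' Verifies that no segment under-declares its read footprint: the
#' derivative response to every variable OUTSIDE a segment's declared read
#' set must be the exact identity (the variable carries itself through and
#' influences nothing else), at tolerance zero. This is checked with one
#' multi-dual evaluation seeded on all out-of-footprint variables, for
#' which the dual part must reproduce the seed matrix bitwise. Also checks
#' that the segment leaves variables outside its write set unchanged.
#'
#' @inheritParams evaluate_model
#' @param seed RNG seed for the value-level probe perturbation.
#' @param scale perturbation magnitude relative to `1 + |x|`.
#' @return Invisibly `TRUE`; stops with the offending segment otherwise.
#' @export
check_footprints <- function(model, x, seed = 0, scale = 0.1) {
  segs <- model$segments
  if (is.null(segs) || !length(segs))
    stop("check_footprints: the model declares no segments", call. = FALSE)
  index <- model$index
  x <- as.numeric(x)
  for (seg in segs) {
    out_vars <- setdiff(index$variables, seg$reads)
    if (length(out_vars)) {
      E <- matrix(0, model$n, length(out_vars))
      for (j in seq_along(out_vars)) E[flat_index(index, out_vars[j]), j] <- 1
      D <- seg$fn(new_dual(x, E))$dual
      if (!identical(D, E))
        stop(sprintf("segment '%s' responds to variables outside its declared read set",
                     seg$name), call. = FALSE)
    }
    wp <- flat_index(index, seg$writes)
    non_wp <- setdiff(seq_len(model$n), wp)
    x2 <- local_seed(seed, x + scale * (1 + abs(x)) * stats::rnorm(model$n))
    y2 <- seg$fn(x2)
    if (!identical(y2[non_wp], x2[non_wp]))
      stop(sprintf("segment '%s' writes outside its declared write set", seg$name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Adjoint dot-product test
#'
#' For random vectors u, w the identity \eqn{\langle M u, w\rangle =
#' \langle u, M^T w\rangle} must hold to rounding error for any consistent
#' tangent-linear/adjoint pair. Reports the relative discrepancy per trial;
#' the test passes when all trials are at or below `tol`.
#'
#' @inheritParams evaluate_model
#' @param trials number of random (u, w) pairs.
#' @param seed RNG seed.
#' @param adjoint which adjoint variant to test.
#' @param tol pass threshold on the relative discrepancy.
#' @return A data frame (trial, lhs, rhs, discrepancy, pass) of class
#'   `"dp_report"` with attribute `"pass"`.
#' @export
dot_product_test <- function(model, x_nl, trials = 20, seed = 0,
                             adjoint = c("auto", "segmented", "multidual", "bruteforce"),
                             tol = 1e-12) {
  stopifnot(trials >= 1)
  adjoint <- match.arg(adjoint)
  if (adjoint == "auto")
    adjoint <- if (!is.null(model$segments)) "segmented" else "multidual"
  adj_fn <- switch(adjoint,
    segmented = function(w) adjoint_segmented(model, x_nl, w),
    multidual = function(w) adjoint_multidual(model, x_nl, w),
    bruteforce = function(w) adjoint_bruteforce(model, x_nl, w))
  n <- model$n
  rows <- local_seed(seed, {
    lapply(seq_len(trials), function(t) {
      u <- stats::rnorm(n); w <- stats::rnorm(n)
      lhs <- sum(evaluate_tlm(model, x_nl, u) * w)
      rhs <- sum(u * adj_fn(w))
      disc <- abs(lhs - rhs) / (abs(lhs) + 1e-30)
      data.frame(trial = t, lhs = lhs, rhs = rhs, discrepancy = disc,
                 pass = disc <= tol)
    })
  })
  rep <- do.call(rbind, rows)
  structure(rep, class = c("dp_report", class(rep)),
            pass = all(rep$pass), adjoint = adjoint, tol = tol)
}

#' @export
print.dp_report <- function(x, ...) {
  cat(sprintf("Adjoint dot-product test (%s adjoint): %s\n",
              attr(x, "adjoint"), if (attr(x, "pass")) "PASS" else "FAIL"))
  cat(sprintf("  trials: %d, max relative discrepancy: %.3e (tolerance %.1e)\n",
              nrow(x), max(x$discrepancy), attr(x, "tol")))
  invisible(x)
}

#' Taylor remainder (gradient) test
#'
#' For a scalar function J with candidate gradient g, the remainder
#' \eqn{|J(x + h d) - J(x) - h \langle g, d\rangle|} must shrink at second
#' order in h when g is the true gradient (first order when it is not).
#' Halves h over `nsteps` steps and fits the log-log slope over the
#' remainders that stand clear of rounding error.
#'
#' @param fn scalar function of the state vector.
#' @param grad candidate gradient at `x` (vector), or a function of x.
#' @param x expansion point.
#' @param direction probe direction; random (unit-normalized) when `NULL`.
#' @param h0 largest step size.
#' @param nsteps number of halvings.
#' @param seed RNG seed for the random direction.
#' @return A data frame (h, remainder) of class `"taylor_report"` with
#'   attributes `"slope"` and `"pass"` (slope at least 1.9).
#' @export
taylor_test <- function(fn, grad, x, direction = NULL, h0 = 1e-2, nsteps = 8, seed = 0) {
  x <- as.numeric(x)
  if (is.null(direction)) {
    direction <- local_seed(seed, stats::rnorm(length(x)))
    direction <- direction / sqrt(sum(direction^2))
  }
  if (all(direction == 0)) stop("taylor_test: direction must be nonzero", call. = FALSE)
  g <- if (is.function(grad)) grad(x) else as.numeric(grad)
  J0 <- fn(x)
  gd <- sum(g * direction)
  h <- h0 / 2^(seq_len(nsteps) - 1)
  r <- vapply(h, function(hk) abs(fn(x + hk * direction) - J0 - hk * gd), numeric(1))
  floor_level <- 1e3 * .Machine$double.eps * (abs(J0) + 1)
  keep <- r > floor_level
  slope <- if (sum(keep) >= 3) {
    unname(stats::coef(stats::lm(log(r[keep]) ~ log(h[keep])))[2])
  } else {
    # everything at rounding level: the remainder is numerically zero,
    # which only an exact gradient achieves
    Inf
  }
  rep <- data.frame(h = h, remainder = r)
  structure(rep, class = c("taylor_report", class(rep)),
            slope = slope, pass = slope >= 1.9)
}

#' @export
print.taylor_report <- function(x, ...) {
  cat(sprintf("Taylor remainder test: %s (log-log slope %.3f, expected about 2)\n",
              if (attr(x, "pass")) "PASS" else "FAIL", attr(x, "slope")))
  invisible(x)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
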