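#' Dual numbers with one or several independent dual parts
#'
#' A dual number is \eqn{d = x + y\epsilon} with \eqn{\epsilon^2 = 0}: the
#' real part carries a function value and the dual part carries, after any
#' sequence of overloaded operations, the exact first derivative scaled by
#' the seed \eqn{y}. Generalizing to \eqn{n} mutually annihilating dual parts
#' (\eqn{\epsilon_i \epsilon_j = 0} for all \eqn{i, j}) lets one evaluation
#' propagate \eqn{n} directional derivatives at once, sharing the real part.
#'
#' `dual()` builds a vectorized dual object: `real` is a numeric vector of
#' length m and `dual` an m-by-s matrix whose column k holds the coefficients
#' of \eqn{\epsilon_k}. With `s = 1` every operation agrees exactly (same
#' floating-point sequence) with classic single-part dual arithmetic.
#'
#' Arithmetic (`+ - * / ^`), comparisons (real parts only), the `Math` group
#' members listed in [dual_call()], `sum`, `max`/`min` (first-argument
#' tie-break), `cumsum`, subsetting and assignment are overloaded, and plain
#' numerics mix freely (they promote to dual with zero dual part), so model
#' code written with ordinary R arithmetic runs unchanged on dual inputs.
#'
#' @param real numeric vector of real parts.
#' @param dual numeric vector (one dual part) or m-by-s matrix (s independent
#'   dual parts); recycled against `real` if a vector. Default: one dual part,
#'   all zero.
#' @return An object of class `"dual"`.
#' @examples
#' d <- dual(3, 1)
#' f <- function(x) 2 * (x - 1)^2 + 3
#' f(d)              # real part f(3) = 11, dual part f'(3) = 8
#' dual_part(dual(0, 1) * dual(0, 1))  # epsilon^2 = 0
#' @export
dual <- function(real, dual = NULL) {
  real <- as.numeric(real)
  m <- length(real)
  if (is.null(dual)) {
    dual <- matrix(0, m, 1L)
  } else if (is.matrix(dual)) {
    if (nrow(dual) != m)
      stop("dual coefficient matrix must have length(real) rows", call. = FALSE)
    storage.mode(dual) <- "double"
  } else {
    dual <- matrix(rep_len(as.numeric(dual), m), m, 1L)
  }
  new_dual(real, dual)
}

new_dual <- function(real, dual) {
  structure(list(real = real, dual = dual), class = "dual")
}

#' @rdname dual
#' @param x object to test or extract from.
#' @export
is_dual <- function(x) inherits(x, "dual")

#' @rdname dual
#' @export
real_part <- function(x) {
  if (is_dual(x)) x$real else as.numeric(x)
}

#' @rdname dual
#' @param drop if `TRUE` and there is a single dual part, return it as a
#'   plain vector rather than a one-column matrix.
#' @export
dual_part <- function(x, drop = TRUE) {
  if (!is_dual(x)) return(if (drop) numeric(length(x)) else matrix(0, length(x), 1L))
  if (drop && ncol(x$dual) == 1L) drop(x$dual) else x$dual
}

#' @rdname dual
#' @export
nseeds <- function(x) if (is_dual(x)) ncol(x$dual) else 1L

#' @export
length.dual <- function(x) length(x$real)

#' @export
format.dual <- function(x, ...) {
  s <- ncol(x$dual)
  if (s == 1L) {
    sprintf("%g%+ge", x$real, x$dual[, 1L])
  } else {
    paste0(
      sprintf("%g", x$real),
      vapply(seq_len(length(x$real)), function(i) {
        paste0(sprintf("%+ge%d", x$dual[i, ], seq_len(s)), collapse = "")
      }, character(1L))
    )
  }
}

#' @export
print.dual <- function(x, ...) {
  cat(sprintf("<dual: %d element(s), %d dual part(s)>\n", length(x$real), ncol(x$dual)))
  print(format(x), quote = FALSE)
  invisible(x)
}

# Conform two operands: common length m and seed count s.
# Numerics keep dual = NULL (treated as zero) to avoid dead allocations.
conform2 <- function(e1, e2, op) {
  d1 <- is_dual(e1); d2 <- is_dual(e2)
  s1 <- if (d1) ncol(e1$dual) else NULL
  s2 <- if (d2) ncol(e2$dual) else NULL
  if (!is.null(s1) && !is.null(s2) && s1 != s2)
    stop(sprintf("dual '%s': operands carry %d and %d dual parts", op, s1, s2),
         call. = FALSE)
  r1 <- if (d1) e1$real else as.numeric(e1)
  r2 <- if (d2) e2$real else as.numeric(e2)
  m1 <- length(r1); m2 <- length(r2)
  m <- max(m1, m2)
  if ((m1 != m && m1 != 1L) || (m2 != m && m2 != 1L))
    stop(sprintf("dual '%s': operand lengths %d and %d are not compatible", op, m1, m2),
         call. = FALSE)
  D1 <- if (d1) e1$dual else NULL
  D2 <- if (d2) e2$dual else NULL
  if (m1 == 1L && m > 1L) { r1 <- rep.int(r1, m); if (!is.null(D1)) D1 <- D1[rep.int(1L, m), , drop = FALSE] }
  if (m2 == 1L && m > 1L) { r2 <- rep.int(r2, m); if (!is.null(D2)) D2 <- D2[rep.int(1L, m), , drop = FALSE] }
  list(r1 = r1, r2 = r2, D1 = D1, D2 = D2, m = m,
       s = if (!is.null(s1)) s1 else s2)
}

zmat <- function(m, s) matrix(0, m, s)

#' @export
Ops.dual <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) {               # unary + / -
    if (op == "+") return(e1)
    if (op == "-") return(new_dual(-e1$real, -e1$dual))
    stop(sprintf("unary '%s' is not defined for dual numbers", op), call. = FALSE)
  }
  if (op %in% c("==", "!=", "<", "<=", ">", ">=")) {
    # ordering and equality act on real parts only: control flow in
    # overloaded model code follows the nonlinear trajectory
    return(get(op)(real_part(e1), real_part(e2)))
  }
  if (op %in% c("&", "|"))
    stop(sprintf("logical '%s' is not defined for dual numbers", op), call. = FALSE)
  cf <- conform2(e1, e2, op)
  r1 <- cf$r1; r2 <- cf$r2; D1 <- cf$D1; D2 <- cf$D2
  switch(op,
    "+" = {
      d <- if (is.null(D1)) D2 else if (is.null(D2)) D1 else D1 + D2
      new_dual(r1 + r2, if (is.null(d)) zmat(cf$m, cf$s) else d)
    },
    "-" = {
      d <- if (is.null(D1)) -D2 else if (is.null(D2)) D1 else D1 - D2
      new_dual(r1 - r2, if (is.null(d)) zmat(cf$m, cf$s) else d)
    },
    "*" = {
      d <- NULL
      if (!is.null(D2)) d <- r1 * D2
      if (!is.null(D1)) d <- if (is.null(d)) r2 * D1 else d + r2 * D1
      new_dual(r1 * r2, d)
    },
    "/" = {
      if (any(r2 == 0))
        stop("dual division: zero real part in denominator", call. = FALSE)
      q <- r1 / r2
      d <- NULL
      if (!is.null(D1)) d <- D1 / r2
      if (!is.null(D2)) d <- if (is.null(d)) -(q / r2) * D2 else d - (q / r2) * D2
      new_dual(q, d)
    },
    "^" = dual_power(r1, r2, D1, D2),
    stop(sprintf("'%s' is not defined for dual numbers", op), call. = FALSE)
  )
}

dual_power <- function(r1, r2, D1, D2) {
  if (is.null(D2)) {                       # dual base, plain exponent
    p <- r2
    bad <- r1 == 0 & p < 1 & p != 0
    if (any(bad))
      stop(sprintf("dual power: 0^%g has an undefined derivative", p[which(bad)[1L]]),
           call. = FALSE)
    slope <- ifelse(p == 0, 0, p * r1^(p - 1))
    return(new_dual(r1^p, slope * D1))
  }
  if (any(r1 <= 0))
    stop(sprintf("dual power: base with non-positive real part %g requires a plain exponent",
                 min(r1)), call. = FALSE)
  v <- r1^r2                               # exponent carries a dual part
  d <- v * log(r1) * D2
  if (!is.null(D1)) d <- d + v * (r2 / r1) * D1
  new_dual(v, d)
}

# derivative table for the Math group: result = f(r), coefficients scaled by f'(r)
#' @export
Math.dual <- function(x, ...) {
  r <- x$real
  chain <- function(fr, fp) new_dual(fr, fp * x$dual)
  dom <- function(ok, what) {
    if (!all(ok))
      stop(sprintf("%s: real part %g outside the domain", what, r[which(!ok)[1L]]),
           call. = FALSE)
  }
  switch(.Generic,
    exp   = chain(exp(r), exp(r)),
    log   = { dom(r > 0, "log");  chain(log(r), 1 / r) },
    sqrt  = { dom(r > 0, "sqrt"); chain(sqrt(r), 0.5 / sqrt(r)) },
    abs   = chain(abs(r), sign(r)),          # sign(0) = 0: symmetric subgradient
    sin   = chain(sin(r),  cos(r)),
    cos   = chain(cos(r), -sin(r)),
    tan   = chain(tan(r), 1 / cos(r)^2),
    atan  = chain(atan(r), 1 / (1 + r^2)),
    sinh  = chain(sinh(r), cosh(r)),
    cosh  = chain(cosh(r), sinh(r)),
    tanh  = chain(tanh(r), 1 / cosh(r)^2),
    expm1 = chain(expm1(r), exp(r)),
    log1p = { dom(r > -1, "log1p"); chain(log1p(r), 1 / (1 + r)) },
    cumsum = new_dual(cumsum(r), apply(x$dual, 2L, cumsum)),
    stop(sprintf("'%s' is not defined for dual numbers", .Generic), call. = FALSE)
  )
}

#' @export
Summary.dual <- function(..., na.rm = FALSE) {
  args <- list(...)
  op <- .Generic
  if (op == "sum") {
    tot <- 0
    for (a in args) tot <- tot + if (is_dual(a))
      new_dual(sum(a$real), matrix(colSums(a$dual), 1L)) else dual(sum(a))
    return(tot)
  }
  if (op %in% c("max", "min")) {
    x <- do.call(dual_c, args)
    i <- if (op == "max") which.max(x$real) else which.min(x$real)
    # which.max/min return the FIRST extreme: ties keep the earlier argument
    return(x[i])
  }
  stop(sprintf("'%s' is not defined for dual numbers", op), call. = FALSE)
}

#' Concatenate dual numbers
#'
#' Plain numerics are promoted to dual numbers with zero dual part; all dual
#' arguments must carry the same number of dual parts.
#' @param ... dual objects and/or numerics.
#' @return A single `dual` object.
#' @export
dual_c <- function(...) {
  args <- list(...)
  s <- 1L
  for (a in args) if (is_dual(a)) { s <- ncol(a$dual); break }
  reals <- vector("list", length(args)); duals <- vector("list", length(args))
  for (k in seq_along(args)) {
    a <- args[[k]]
    if (is_dual(a)) {
      if (ncol(a$dual) != s)
        stop("dual_c: mismatched numbers of dual parts", call. = FALSE)
      reals[[k]] <- a$real; duals[[k]] <- a$dual
    } else {
      reals[[k]] <- as.numeric(a); duals[[k]] <- zmat(length(a), s)
    }
  }
  new_dual(unlist(reals, use.names = FALSE), do.call(rbind, duals))
}

#' @export
`[.dual` <- function(x, i) new_dual(x$real[i], x$dual[i, , drop = FALSE])

#' @export
`[<-.dual` <- function(x, i, value) {
  if (is_dual(value)) {
    if (ncol(value$dual) != ncol(x$dual))
      stop("dual assignment: mismatched numbers of dual parts", call. = FALSE)
    x$real[i] <- value$real
    x$dual[i, ] <- value$dual
  } else {
    x$real[i] <- as.numeric(value)
    x$dual[i, ] <- 0
  }
  x
}

#' Elementwise maximum and minimum with a deterministic tie-break
#'
#' Overloaded-AD analogues of [pmax()]/[pmin()] for dual numbers: the
#' selection is made on real parts only and an exact tie keeps the FIRST
#' argument (and its dual part), matching the left-to-right evaluation of a
#' hand-written conditional. Plain numerics are accepted and promoted.
#'
#' @param a,b dual objects or numerics of compatible length.
#' @return A `dual` if either argument is dual, otherwise numeric.
#' @export
dpmax <- function(a, b) dual_select(a, b, take_first = function(ra, rb) ra >= rb)

#' @rdname dpmax
#' @export
dpmin <- function(a, b) dual_select(a, b, take_first = function(ra, rb) ra <= rb)

dual_select <- function(a, b, take_first) {
  if (!is_dual(a) && !is_dual(b)) {
    keep <- take_first(a, b)
    return(ifelse(keep, a, b))
  }
  cf <- conform2(a, b, "pmax/pmin")
  keep <- take_first(cf$r1, cf$r2)
  D1 <- if (is.null(cf$D1)) zmat(cf$m, cf$s) else cf$D1
  D2 <- if (is.null(cf$D2)) zmat(cf$m, cf$s) else cf$D2
  new_dual(ifelse(keep, cf$r1, cf$r2),
           D1 * keep + D2 * !keep)
}

#' Apply a named elementary function to a dual number
#'
#' Thin functional interface over the overloaded elementary functions:
#' `result = f(real)` with dual coefficients scaled by the analytic
#' `f'(real)`. Supported names: `exp`, `log`, `sqrt`, `sin`, `cos`, `tan`,
#' `tanh`, `abs`, `neg`, and `power` (which takes the exponent `p`).
#'
#' @param fname function name (character).
#' @param x dual object (plain numerics are promoted).
#' @param p exponent, used only by `fname = "power"`.
#' @return A `dual` object.
#' @export
dual_call <- function(fname, x, p = NULL) {
  if (!is_dual(x)) x <- dual(x)
  switch(fname,
    exp = exp(x), log = log(x), sqrt = sqrt(x), sin = sin(x), cos = cos(x),
    tan = tan(x), tanh = tanh(x), abs = abs(x), neg = -x,
    power = {
      if (is.null(p)) stop("dual_call: 'power' needs an exponent p", call. = FALSE)
      x^p
    },
    stop(sprintf("dual_call: unsupported function '%s'", fname), call. = FALSE)
  )
}
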