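#' Lossless text serialization of model objects
#'
#' States, trajectories, observation sets, and assimilation tables are
#' written as tab-separated text with a header. Numbers are encoded with the
#' shortest decimal representation that round-trips to the identical
#' double-precision value, so write-then-read is bitwise lossless.
#'
#' @param x numeric vector to encode.
#' @return Character vector of decimal encodings.
#' @keywords internal
shortest_roundtrip <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.16g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    out[i] <- s
  }
  out
}

#' Read and write flat states as delimited text
#'
#' Columns: `cell`, `variable`, `value`; cell-major row order.
#' @param state flat state vector.
#' @param index a [state_index()].
#' @param path file path.
#' @export
write_state <- function(state, index, path) {
  df <- data.frame(cell = rep(seq_len(index$n_cells), each = index$n_vars),
                   variable = rep(index$variables, index$n_cells),
                   value = shortest_roundtrip(as.numeric(state)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path, index) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "character"))
  iv <- match(df$variable, index$variables)
  if (anyNA(iv))
    stop(sprintf("read_state: unknown variable '%s' in %s",
                 df$variable[which(is.na(iv))[1L]], path), call. = FALSE)
  x <- numeric(index$n)
  x[(df$cell - 1L) * index$n_vars + iv] <- as.numeric(df$value)
  x
}

#' Read and write trajectories as delimited text
#'
#' Columns: `time` (step index from 0), `cell`, `variable`, `value`.
#' @param traj n x (nsteps+1) trajectory matrix.
#' @inheritParams write_state
#' @export
write_trajectory <- function(traj, index, path) {
  nt <- ncol(traj)
  df <- data.frame(time = rep(0:(nt - 1L), each = index$n),
                   cell = rep(rep(seq_len(index$n_cells), each = index$n_vars), nt),
                   variable = rep(rep(index$variables, index$n_cells), nt),
                   value = shortest_roundtrip(as.vector(traj)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, index) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "character", "character"))
  times <- sort(unique(df$time))
  traj <- matrix(NA_real_, index$n, length(times))
  pos <- (df$cell - 1L) * index$n_vars + match(df$variable, index$variables)
  traj[cbind(pos, match(df$time, times))] <- as.numeric(df$value)
  traj
}

#' Read and write observation sets as delimited text
#'
#' Columns: `time`, `cell`, `quantity`, `value`, `sigma`.
#' @param obs observation data frame.
#' @param path file path.
#' @export
write_observations <- function(obs, path) {
  df <- data.frame(time = shortest_roundtrip(obs$time), cell = obs$cell,
                   quantity = obs$quantity,
                   value = shortest_roundtrip(obs$value),
                   sigma = shortest_roundtrip(obs$sigma))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "character"))
  data.frame(time = as.numeric(df$time), cell = df$cell, quantity = df$quantity,
             value = as.numeric(df$value), sigma = as.numeric(df$sigma))
}

config_schema <- function() {
  list(
    grid = list(n_layers = "numeric", dz = "numeric", kv = "numeric", dt = "numeric"),
    params = c(lapply(formals(nemuro_params), function(...) "numeric")),
    forcing = list(surface_irradiance = "numeric"),
    assimilation = list(n_outer = "numeric", n_inner = "numeric",
                        cg_tol = "numeric", precondition = "logical",
                        window = "numeric", sigma_b_frac = "numeric"),
    twin = list(perturb_scale = "numeric", noise_dense = "numeric",
                noise_chl = "numeric", mask_fraction = "numeric",
                dense_quantity = "character", obs_every = "numeric",
                seed = "numeric")
  )
}

#' Run configuration: defaults, validation, file round-trip
#'
#' The configuration is a nested key-value structure (YAML on disk) with
#' sections `grid`, `params`, `forcing`, `assimilation`, and `twin`. Every
#' key is validated against the schema; unknown keys are rejected by name.
#' Values omitted from a file fall back to the package defaults.
#'
#' @return `default_config()`: the full default configuration list.
#' @export
default_config <- function() {
  list(
    grid = list(n_layers = 5, dz = 5, kv = 1e-4, dt = 3600),
    params = lapply(formals(nemuro_params), eval),
    forcing = list(surface_irradiance = 150),
    assimilation = list(n_outer = 2, n_inner = 10, cg_tol = 1e-10,
                        precondition = TRUE, window = 96, sigma_b_frac = 0.3),
    twin = list(perturb_scale = 0.2, noise_dense = 0.1, noise_chl = 0.05,
                mask_fraction = 0.4, dense_quantity = "NO3", obs_every = 6,
                seed = 0)
  )
}

#' @rdname default_config
#' @param config a (possibly partial) configuration list.
#' @return `validate_config()`: the merged, validated configuration.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  merged <- default_config()
  if (!is.list(config)) stop("config must be a key-value structure", call. = FALSE)
  for (section in names(config)) {
    if (!section %in% names(schema))
      stop(sprintf("unknown configuration section '%s'", section), call. = FALSE)
    entries <- config[[section]]
    if (!is.list(entries))
      stop(sprintf("configuration section '%s' must hold key-value pairs", section), call. = FALSE)
    for (key in names(entries)) {
      if (!key %in% names(schema[[section]]))
        stop(sprintf("unknown configuration key '%s.%s'", section, key), call. = FALSE)
      want <- schema[[section]][[key]]
      val <- entries[[key]]
      ok <- switch(want,
                   numeric = is.numeric(val),
                   logical = is.logical(val),
                   character = is.character(val))
      if (!ok)
        stop(sprintf("configuration key '%s.%s' must be %s", section, key, want), call. = FALSE)
      merged[[section]][[key]] <- val
    }
  }
  merged
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build model objects from a validated configuration
#'
#' @param config a validated configuration (see [validate_config()]).
#' @return List with `params`, `grid`, `model`, `minimizer`, `twin`,
#'   `window`, `sigma_b_frac`, and `surface_irradiance`.
#' @export
config_objects <- function(config) {
  config <- validate_config(config)
  params <- do.call(nemuro_params, config$params)
  grid <- do.call(column_grid, config$grid)
  a <- config$assimilation
  list(params = params, grid = grid,
       model = nemuro_model(params, grid, config$forcing$surface_irradiance),
       minimizer = minimizer_config(a$n_outer, a$n_inner, a$cg_tol, a$precondition),
       twin = do.call(twin_config, config$twin),
       window = a$window, sigma_b_frac = a$sigma_b_frac,
       surface_irradiance = config$forcing$surface_irradiance)
}
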