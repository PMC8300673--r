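# Euler-Maruyama simulation of the model library. The two bundled model
# families (linear/OU, Rosenzweig-MacArthur metacommunity) run through a
# compiled stepper; arbitrary user models fall back to a pure-R loop.

#' Noise specification
#'
#' @param sigma Per-variable noise amplitudes (units variable/sqrt(time));
#'   recycled to the model dimension.
#' @param mode `"additive"` (state-independent) or `"multiplicative"`
#'   (amplitude `sigma * x`).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sigma, mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  sigma <- as.numeric(sigma)
  if (any(sigma < 0) || any(!is.finite(sigma))) {
    stop("noise amplitudes must be finite and nonnegative")
  }
  structure(list(sigma = sigma, mode = mode), class = "noise_spec")
}

#' Simulation configuration
#'
#' @param dt Integration step (time units), > 0.
#' @param n_samples Number of retained samples (>= 2).
#' @param stride Keep every `stride`-th post-burn-in step (default 1, no
#'   thinning).
#' @param burn_in Number of initial steps discarded.
#' @param seed Integer seed; all randomness of a run flows from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dt, n_samples, stride = 1L, burn_in = 0L, seed = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) stop("n_samples must be >= 2")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be >= 1")
  burn_in <- as.integer(burn_in)
  if (is.na(burn_in) || burn_in < 0L) stop("burn_in must be >= 0")
  structure(list(dt = dt, n_samples = n_samples, stride = stride,
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "sim_config")
}

#' Fluctuation matrix implied by a noise specification
#'
#' Under the `-2` normalisation of the Lyapunov relation
#' `J Gamma + Gamma J' = -2 D`, the diagonal fluctuation matrix that the
#' simulated linear system satisfies exactly is `D = diag(sigma^2 / 2)`
#' for additive noise and `D = diag(sigma^2 x*^2 / 2)` for
#' multiplicative noise evaluated at the steady state.
#'
#' @param noise A [noise_spec()].
#' @param xstar Steady state (required for multiplicative noise).
#' @param n Model dimension (to recycle scalar amplitudes); defaults to
#'   `length(xstar)` or `length(sigma)`.
#' @return A diagonal `N` x `N` matrix.
#' @export
fluctuation_from_noise <- function(noise, xstar = NULL, n = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  if (inherits(xstar, "steady_state")) xstar <- xstar$x
  if (is.null(n)) n <- if (!is.null(xstar)) length(xstar) else length(noise$sigma)
  s <- rep_len(noise$sigma, n)
  if (noise$mode == "multiplicative") {
    if (is.null(xstar)) stop("multiplicative noise needs the steady state")
    s <- s * abs(xstar)
  }
  diag(s^2 / 2, nrow = n)
}

.native_kind <- function(model) {
  if (is.null(model$native)) NULL else model$native
}

# assemble the native-data list handed to the compiled stepper
.native_payload <- function(model) {
  if (identical(model$native, "linear")) {
    list(jacobian = model$native_data$jacobian)
  } else if (identical(model$native, "rm")) {
    list(params = as.numeric(model$params[c("r", "K", "a", "h", "eps",
                                            "m", "g", "delta_b",
                                            "delta_c")]),
         adjacency = model$native_data$adjacency + 0)
  } else {
    NULL
  }
}

#' Simulate a model with noise by the Euler-Maruyama method
#'
#' Iterates `x <- x + f(x) dt + sigma_eff(x) sqrt(dt) xi` with
#' independent standard-normal `xi` per variable and step, discards
#' `burn_in` steps, and retains every `stride`-th state thereafter.
#' Runs are exactly reproducible from `config$seed`.
#'
#' Models on the positive orthant are not clipped: if any variable
#' crosses below `floor` the run is rejected and restarted with a seed
#' derived deterministically from `config$seed` (the retry count is
#' recorded in the result), because clipping would bias the covariance
#' the reconstruction relies on.
#'
#' @param model A `dyn_model`.
#' @param noise A [noise_spec()].
#' @param config A [sim_config()].
#' @param x0 Initial state (defaults to the origin for linear models).
#' @param floor Lower bound below which a trajectory is rejected;
#'   defaults to 0 for positive-orthant models and `-Inf` otherwise.
#' @param max_retries Maximum rejection-resampling attempts (default 5).
#' @return Object of class `sim_ts`: `times`, `values`
#'   (`n_samples` x `N`), `labels`, `config`, `noise`, `retries`,
#'   and `param_trace`/`param_name` when run through [parameter_ramp()].
#' @export
euler_maruyama <- function(model, noise, config, x0 = NULL,
                           floor = NULL, max_retries = 5L) {
  .simulate_impl(model, noise, config, x0, floor, max_retries,
                 ramp = NULL)
}

#' Simulate while slowly ramping one parameter
#'
#' Identical to [euler_maruyama()] except that the named model
#' parameter is interpolated linearly in time across the post-burn-in
#' portion of the run (held at `from` during burn-in). The parameter
#' value at each retained sample is returned alongside the states.
#'
#' @inheritParams euler_maruyama
#' @param name Name of the parameter to ramp.
#' @param from,to Start and end values.
#' @return A `sim_ts` with `param_trace` and `param_name` set.
#' @export
parameter_ramp <- function(model, name, from, to, noise, config,
                           x0 = NULL, floor = NULL, max_retries = 5L) {
  stopifnot(inherits(model, "dyn_model"))
  if (!name %in% names(model$params)) {
    stop("unknown parameter '", name, "'; model has: ",
         paste(names(model$params), collapse = ", "))
  }
  .simulate_impl(model, noise, config, x0, floor, max_retries,
                 ramp = list(name = name, from = from, to = to))
}

.simulate_impl <- function(model, noise, config, x0, floor, max_retries,
                           ramp) {
  stopifnot(inherits(model, "dyn_model"))
  stopifnot(inherits(noise, "noise_spec"))
  stopifnot(inherits(config, "sim_config"))
  n <- model$n
  if (is.null(x0)) {
    if (identical(model$native, "linear")) x0 <- numeric(n)
    else stop("x0 is required for this model")
  }
  if (inherits(x0, "steady_state")) x0 <- x0$x
  x0 <- as.numeric(x0)
  if (length(x0) != n) stop("x0 has wrong length")
  sigma <- rep_len(noise$sigma, n)
  if (is.null(floor)) floor <- if (isTRUE(model$positive)) 0 else -Inf

  kind <- .native_kind(model)
  use_native <- !is.null(kind) && (is.null(ramp) || kind == "rm")
  ramp_index <- -1L
  ramp_from <- 0
  ramp_to <- 0
  params <- model$params
  if (!is.null(ramp)) {
    ramp_from <- ramp$from
    ramp_to <- ramp$to
    if (use_native) {
      ramp_index <- match(ramp$name,
                          c("r", "K", "a", "h", "eps", "m", "g",
                            "delta_b", "delta_c")) - 1L
    }
  }

  retries <- 0L
  repeat {
    seed <- config$seed + 7919L * retries
    set.seed(seed)
    if (use_native) {
      out <- em_native(kind, .native_payload(model), x0, config$dt,
                       config$n_samples, config$stride, config$burn_in,
                       sigma, noise$mode == "multiplicative",
                       ramp_index, ramp_from, ramp_to, floor)
    } else {
      out <- .em_r_loop(model, x0, config, sigma,
                        noise$mode == "multiplicative", ramp, floor)
    }
    if (out$status == 0L) break
    if (out$status == 2L) {
      stop("state became non-finite at step ", out$step,
           "; reduce dt or the noise amplitude")
    }
    retries <- retries + 1L
    if (retries > max_retries) {
      stop("trajectory crossed the floor (", floor, ") at step ",
           out$step, " in ", max_retries + 1L,
           " attempts; the noise pushes the system out of the ",
           "linearisation regime")
    }
  }

  times <- config$dt * (config$burn_in + config$stride *
                          seq_len(config$n_samples))
  ts <- structure(
    list(times = times, values = out$values, labels = model$labels,
         config = config, noise = noise, retries = retries,
         param_trace = NULL, param_name = NULL),
    class = "sim_ts"
  )
  if (!is.null(ramp)) {
    ts$param_trace <- if (!is.null(out$param_trace) &&
                          length(out$param_trace)) {
      out$param_trace
    } else {
      # analytic trace for the R path
      frac <- (config$stride * seq_len(config$n_samples) - 1) /
        max(1, config$n_samples * config$stride - 1)
      ramp$from + frac * (ramp$to - ramp$from)
    }
    ts$param_name <- ramp$name
  }
  ts
}

# Pure-R stepper for models without a compiled kernel (small runs only).
.em_r_loop <- function(model, x0, config, sigma, multiplicative, ramp,
                       floor) {
  n <- model$n
  total <- config$burn_in + config$n_samples * config$stride
  denom <- max(1, config$n_samples * config$stride - 1)
  values <- matrix(NA_real_, config$n_samples, n)
  ptrace <- numeric(config$n_samples)
  params <- model$params
  x <- x0
  sdt <- sqrt(config$dt)
  k <- 0L
  for (t in seq_len(total)) {
    if (!is.null(ramp)) {
      frac <- if (t <= config$burn_in) 0 else (t - 1 - config$burn_in) / denom
      params[[ramp$name]] <- ramp$from + frac * (ramp$to - ramp$from)
    }
    f <- model$rhs(x, params)
    s <- if (multiplicative) sigma * x else sigma
    x <- x + f * config$dt + s * sdt * stats::rnorm(n)
    if (!all(is.finite(x))) {
      return(list(status = 2L, step = t, values = values,
                  param_trace = ptrace))
    }
    if (any(x < floor)) {
      return(list(status = 1L, step = t, values = values,
                  param_trace = ptrace))
    }
    if (t > config$burn_in &&
        (t - config$burn_in) %% config$stride == 0L) {
      k <- k + 1L
      values[k, ] <- x
      if (!is.null(ramp)) ptrace[k] <- params[[ramp$name]]
    }
  }
  list(status = 0L, step = -1L, values = values, param_trace = ptrace)
}

#' @export
print.sim_ts <- function(x, ...) {
  cat("Simulated time series: ", nrow(x$values), " samples x ",
      ncol(x$values), " variables, t in [",
      signif(x$times[1], 4), ", ", signif(max(x$times), 4), "]\n",
      sep = "")
  if (!is.null(x$param_name)) {
    cat("  ramped parameter: ", x$param_name, " from ",
        signif(x$param_trace[1], 4), " to ",
        signif(x$param_trace[length(x$param_trace)], 4), "\n", sep = "")
  }
  if (x$retries > 0) cat("  rejected trajectories before success: ",
                         x$retries, "\n", sep = "")
  invisible(x)
}
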