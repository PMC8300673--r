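# From time series to early warning signals: covariance estimation,
# whole-series and sliding-window reconstruction, and transect
# experiments against the ground truth of the model library.

#' Sample covariance of a fluctuation time series
#'
#' `Gamma = 1/(n-1) * sum_k (x_k - mu)(x_k - mu)'` with `mu` either the
#' sample mean or a supplied steady state. The unbiased `(n-1)`
#' normalisation is immaterial at the series lengths the method needs
#' but is documented for small-window use.
#'
#' @param x A `sim_ts` or an `n` x `N` numeric matrix.
#' @param center `"mean"` (default) or `"given"`.
#' @param xstar Steady state to centre on when `center = "given"`.
#' @return A symmetric positive-semidefinite `N` x `N` matrix.
#' @export
estimate_covariance <- function(x, center = c("mean", "given"),
                                xstar = NULL) {
  center <- match.arg(center)
  if (inherits(x, "sim_ts")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples to estimate a covariance")
  if (!all(is.finite(x))) stop("time series contains non-finite values")
  if (center == "mean") {
    stats::cov(x)
  } else {
    if (inherits(xstar, "steady_state")) xstar <- xstar$x
    if (is.null(xstar) || length(xstar) != ncol(x)) {
      stop("center = \"given\" needs xstar of length ", ncol(x))
    }
    xc <- sweep(x, 2L, xstar)
    crossprod(xc) / (nrow(x) - 1)
  }
}

#' Reconstruct a Jacobian directly from a time series
#'
#' Composition of [estimate_covariance()] and [reconstruct_jacobian()].
#'
#' @param ts A `sim_ts` or numeric matrix of fluctuations.
#' @param pattern A [zero_pattern()].
#' @param D Fluctuation matrix of the noise (known or from
#'   [fluctuation_from_noise()]).
#' @param center,xstar Passed to [estimate_covariance()].
#' @param ... Passed to [reconstruct_jacobian()].
#' @return A `jac_reconstruction` with an `n_samples` field.
#' @export
reconstruct_from_series <- function(ts, pattern, D,
                                    center = c("mean", "given"),
                                    xstar = NULL, ...) {
  G <- estimate_covariance(ts, center = center, xstar = xstar)
  if (max(diag(G)) <= 0) {
    stop("degenerate covariance: the series carries no fluctuations")
  }
  res <- reconstruct_jacobian(G, D, pattern, ...)
  res$n_samples <- if (inherits(ts, "sim_ts")) nrow(ts$values) else nrow(ts)
  res
}

#' Sliding-window specification
#'
#' @param tau Window length in samples (`1 < tau <= n`).
#' @param stride Shift between consecutive windows (default `tau / 4`).
#' @param placement Where the estimate is anchored on the time axis:
#'   at the window `"end"` (default) or `"centre"`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(tau, stride = NULL,
                        placement = c("end", "centre")) {
  placement <- match.arg(placement)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 2L) stop("tau must be at least 2 samples")
  if (is.null(stride)) stride <- max(1L, tau %/% 4L)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be >= 1")
  structure(list(tau = tau, stride = stride, placement = placement),
            class = "window_spec")
}

#' Leading-eigenvalue trajectory from sliding-window reconstruction
#'
#' Reconstructs the Jacobian in a sliding window of `tau` samples and
#' returns the leading-eigenvalue estimate per window. Each window is
#' mean-centred individually, which removes the slow drift of the
#' operating point when a parameter is ramped.
#'
#' @param ts A `sim_ts` (or numeric matrix).
#' @param window A [window_spec()].
#' @param pattern A [zero_pattern()].
#' @param D Fluctuation matrix (held fixed across windows).
#' @param ... Passed to [reconstruct_jacobian()].
#' @return Object of class `ews_trajectory`: a data.frame with columns
#'   `anchor_time`, `re_leading`, `im_leading`, `residual_norm`, and
#'   `param` when the series carries a ramp trace.
#' @export
sliding_window_ews <- function(ts, window, pattern, D, ...) {
  stopifnot(inherits(window, "window_spec"))
  values <- if (inherits(ts, "sim_ts")) ts$values else as.matrix(ts)
  times <- if (inherits(ts, "sim_ts")) ts$times else seq_len(nrow(values))
  ptrace <- if (inherits(ts, "sim_ts")) ts$param_trace else NULL
  n <- nrow(values)
  tau <- window$tau
  if (tau > n) stop("window length tau (", tau,
                    ") exceeds series length (", n, ")")
  starts <- seq.int(1L, n - tau + 1L, by = window$stride)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + tau - 1L)
    anchor <- if (window$placement == "end") idx[tau] else
      idx[ceiling(tau / 2)]
    rec <- reconstruct_from_series(values[idx, , drop = FALSE],
                                   pattern, D, ...)
    data.frame(anchor_time = times[anchor],
               re_leading = Re(rec$leading_eigenvalue),
               im_leading = Im(rec$leading_eigenvalue),
               residual_norm = rec$residual_norm,
               param = if (!is.null(ptrace)) ptrace[anchor] else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(ptrace)) out$param <- NULL
  attr(out, "window") <- window
  class(out) <- c("ews_trajectory", "data.frame")
  out
}

#' Locate a bifurcation from a leading-eigenvalue trajectory
#'
#' Estimates the parameter value at which a reconstructed leading
#' real part reaches zero. Post-bifurcation estimates concentrate at
#' (numerically just below) zero because the system sits on an
#' attractor whose leading exponent is zero, so a literal sign flip is
#' ill-defined at the estimator's resolution. Instead a one-knot hinge
#' model `y(p) = min(b * (p - t), 0)` (a line rising to zero, then a
#' plateau at zero) is fitted by least squares over the knot `t`; the
#' knot is the estimated crossing. For a curve that genuinely changes
#' sign (e.g. the analytic ground truth) the crossing is located by
#' linear interpolation of the sign change instead.
#'
#' @param param Ordered parameter values.
#' @param value Leading-eigenvalue real parts along `param`.
#' @param method `"auto"` (default) interpolates when a sign change is
#'   present and otherwise falls back to the hinge fit; `"interpolate"`
#'   and `"hinge"` force a method.
#' @return The estimated crossing parameter (`NA` if the curve never
#'   approaches zero from below).
#' @export
locate_crossing <- function(param, value,
                            method = c("auto", "interpolate", "hinge")) {
  method <- match.arg(method)
  stopifnot(length(param) == length(value), length(param) >= 3)
  ord <- order(param)
  param <- param[ord]
  value <- value[ord]
  sign_change <- which(value[-length(value)] < 0 & value[-1] >= 0)
  if (method == "interpolate" ||
      (method == "auto" && length(sign_change))) {
    if (!length(sign_change)) return(NA_real_)
    i <- sign_change[1L]
    param[i] + (0 - value[i]) * (param[i + 1L] - param[i]) /
      (value[i + 1L] - value[i])
  } else {
    span <- diff(range(param))
    cand <- seq(param[1L], param[length(param)] + span / 2,
                length.out = 400L)
    sse <- vapply(cand, function(t) {
      pre <- param < t
      s1 <- if (sum(pre) >= 2) {
        b <- sum(value[pre] * (param[pre] - t)) /
          sum((param[pre] - t)^2)
        sum((value[pre] - b * (param[pre] - t))^2)
      } else {
        sum(value[pre]^2)
      }
      s1 + sum(value[!pre]^2)
    }, numeric(1))
    cand[which.min(sse)]
  }
}

#' Transect experiment: reconstruction accuracy against ground truth
#'
#' Walks a parameter grid towards (and possibly across) a bifurcation.
#' At each grid point the steady state is tracked by continuation, the
#' exact Jacobian and its leading eigenvalue are computed as ground
#' truth, a noisy time series is simulated, and the Jacobian is
#' reconstructed from it. Grid points whose steady state is unstable
#' are flagged rather than suppressed: there the analytic eigenvalue
#' describes a state the simulation has departed from, so the
#' comparison is not meaningful.
#'
#' @param model_factory Function mapping a grid value to a `dyn_model`.
#' @param grid Numeric vector of parameter values (walked in order).
#' @param noise A [noise_spec()], or a function of the steady-state
#'   vector returning one (e.g. amplitudes proportional to `x*`).
#' @param config A [sim_config()]; the seed is offset per grid point so
#'   points get independent noise.
#' @param pattern A [zero_pattern()].
#' @param surrogate `"nonlinear"` (default) simulates the full model;
#'   `"linear"` simulates the Ornstein-Uhlenbeck surrogate `xdot = J x`
#'   with the true Jacobian, isolating estimation error from
#'   nonlinearity.
#' @param x0 Starting point for the first steady-state search.
#' @param ... Passed to [reconstruct_jacobian()].
#' @return Object of class `transect_result`: a data.frame with one row
#'   per grid point: `param`, `true_re`, `true_im`, `rec_re`, `rec_im`,
#'   `error` (modulus of the leading-eigenvalue mismatch), `stable`,
#'   `note`.
#' @export
transect_experiment <- function(model_factory, grid, noise, config,
                                pattern, surrogate = c("nonlinear",
                                                       "linear"),
                                x0 = NULL, ...) {
  surrogate <- match.arg(surrogate)
  if (!length(grid)) stop("grid must be nonempty")
  rows <- vector("list", length(grid))
  x_prev <- x0
  for (i in seq_along(grid)) {
    g <- grid[i]
    model <- model_factory(g)
    ss <- tryCatch(find_steady_state(model, x_prev),
                   error = function(e) e)
    if (inherits(ss, "error")) {
      rows[[i]] <- data.frame(param = g, true_re = NA_real_,
                              true_im = NA_real_, rec_re = NA_real_,
                              rec_im = NA_real_, error = NA_real_,
                              stable = NA,
                              note = paste("steady state failed:",
                                           conditionMessage(ss)))
      next
    }
    x_prev <- ss$x
    J_true <- numeric_jacobian(model, ss)
    lam_true <- jacobian_spectrum(J_true)$leading
    stable <- Re(lam_true) < 0
    ns <- if (is.function(noise)) noise(ss$x) else noise
    D <- fluctuation_from_noise(ns, xstar = ss, n = model$n)
    cfg <- config
    cfg$seed <- config$seed + 131L * (i - 1L)
    sim_model <- if (surrogate == "linear") linear_model(J_true) else model
    sim_x0 <- if (surrogate == "linear") numeric(model$n) else ss$x
    rec <- tryCatch({
      ts <- euler_maruyama(sim_model, ns, cfg, x0 = sim_x0)
      reconstruct_from_series(ts, pattern, D, ...)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      rows[[i]] <- data.frame(param = g, true_re = Re(lam_true),
                              true_im = Im(lam_true), rec_re = NA_real_,
                              rec_im = NA_real_, error = NA_real_,
                              stable = stable,
                              note = paste("simulation failed:",
                                           conditionMessage(rec)))
      next
    }
    lam_rec <- rec$leading_eigenvalue
    rows[[i]] <- data.frame(
      param = g, true_re = Re(lam_true), true_im = Im(lam_true),
      rec_re = Re(lam_rec), rec_im = Im(lam_rec),
      error = Mod(lam_rec - lam_true), stable = stable,
      note = if (stable) "" else "unstable steady state"
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("transect_result", "data.frame")
  out
}
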