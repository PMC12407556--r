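new_trajectory <- function(times, states, dt, method, diverged = FALSE,
                           extra = list()) {
  structure(c(list(times = times, states = states, dt = dt, method = method,
                   diverged = diverged), extra),
            class = "coopnet_trajectory")
}

#' @export
print.coopnet_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points, %d units, dt = %g (%s)%s\n",
              length(x$times), ncol(x$states), x$dt, x$method,
              if (isTRUE(x$diverged)) " [DIVERGED]" else ""))
  invisible(x)
}

#' Integrate a linear rate network
#'
#' General-purpose time integration of `tau dx/dt = -x + W_rec x + W_ff r(t)`
#' with the explicit Euler or midpoint (second-order Runge-Kutta) method.
#' This routine works for any `coopnet_network`; the specialised compiled
#' integrators ([simulate_ring()], [simulate_torus()], [sfa_integrate()],
#' [delayed_integrate()]) are much faster for the structured topologies and
#' are cross-validated against this one in the test suite.
#'
#' Divergence (loss of finiteness or activity beyond an overflow guard) flags
#' the trajectory instead of raising an error.
#'
#' @param net a `coopnet_network`.
#' @param input constant input vector, or a function of time returning one.
#' @param x0 initial state (default zero).
#' @param dt step size in units of `tau` (default 0.01).
#' @param T integration horizon.
#' @param method `"midpoint"` (default) or `"euler"`.
#' @param record_stride store every `record_stride`-th state (default 1).
#' @return A `coopnet_trajectory` with fields `times` and `states`
#'   (rows = time points).
#' @export
integrate_rate <- function(net, input, x0 = NULL, dt = 0.01, T,
                           method = c("midpoint", "euler"), record_stride = 1) {
  method <- match.arg(method)
  if (!is.numeric(dt) || dt <= 0 || T < dt) stop_param("need dt > 0 and T >= dt")
  n <- net$N
  x <- x0 %||% numeric(n)
  if (anyNA(x)) stop_param("NaN in initial state")
  const_input <- !is.function(input)
  if (const_input) {
    if (anyNA(input)) stop_param("NaN in input")
    h_const <- as.numeric(net$W_ff %*% input)
  }
  drive <- function(t) {
    if (const_input) h_const else as.numeric(net$W_ff %*% input(t))
  }
  n_steps <- round(T / dt)
  keep <- seq(0, n_steps, by = record_stride)
  states <- matrix(NA_real_, length(keep), n)
  states[1, ] <- x
  tau <- net$tau
  W <- net$W_rec
  diverged <- FALSE
  row <- 1
  for (s in seq_len(n_steps)) {
    t0 <- (s - 1) * dt
    f1 <- (-x + as.numeric(W %*% x) + drive(t0)) / tau
    if (method == "midpoint") {
      xm <- x + 0.5 * dt * f1
      x <- x + dt * (-xm + as.numeric(W %*% xm) + drive(t0 + dt / 2)) / tau
    } else {
      x <- x + dt * f1
    }
    if (s %% record_stride == 0) {
      row <- row + 1
      states[row, ] <- x
    }
    if (!all(is.finite(x)) || max(abs(x)) > 1e12) { diverged <- TRUE; break }
  }
  if (diverged) states <- states[seq_len(row), , drop = FALSE]
  new_trajectory(times = keep[seq_len(nrow(states))] * dt, states = states,
                 dt = dt, method = method, diverged = diverged)
}

new_loss_curve <- function(times, values, diverged = FALSE) {
  structure(list(times = times, values = values, diverged = diverged),
            class = "coopnet_loss")
}

#' @export
print.coopnet_loss <- function(x, ...) {
  cat(sprintf("L1 loss curve: %d points, horizon %g, L(0) = %g%s\n",
              length(x$times), max(x$times), x$values[1],
              if (isTRUE(x$diverged)) " [DIVERGED]" else ""))
  invisible(x)
}

#' L1 loss relative to a target state
#'
#' `L(t) = |x(t) - x_target|_1`, the L1 norm of the deviation of the
#' trajectory from the target (steady-state) activity.
#'
#' @param traj a `coopnet_trajectory`.
#' @param x_target target activity vector.
#' @return A `coopnet_loss` object.
#' @export
l1_loss_curve <- function(traj, x_target) {
  if (!inherits(traj, "coopnet_trajectory")) stop_param("traj must be a trajectory")
  if (length(x_target) != ncol(traj$states)) stop_param("dimension mismatch")
  vals <- rowSums(abs(sweep(traj$states, 2, x_target)))
  new_loss_curve(traj$times, vals, diverged = traj$diverged)
}

#' Measure the response time from a loss curve
#'
#' The response time is the earliest time after which the loss stays below
#' `exp(-1)` times its initial value for the rest of the horizon (last
#' up-crossing rule; a transient re-crossing above the threshold moves the
#' measurement to the final crossing).
#'
#' @param loss a `coopnet_loss`, or a numeric vector of loss values (then
#'   `times` must be given).
#' @param times time stamps if `loss` is a bare vector.
#' @param threshold_frac crossing fraction of the initial loss
#'   (default `exp(-1)`).
#' @return A list of class `coopnet_response_time` with `value` (time; `NA`
#'   if the loss never settles below threshold within the horizon),
#'   `converged`, `horizon`, and `criterion`.
#' @export
measure_response_time <- function(loss, times = NULL,
                                  threshold_frac = exp(-1)) {
  if (inherits(loss, "coopnet_loss")) {
    times <- loss$times
    vals <- loss$values
  } else {
    vals <- as.numeric(loss)
    if (is.null(times)) stop_param("times required for a bare loss vector")
  }
  if (length(vals) < 2) stop_param("loss curve too short")
  thr <- vals[1] * threshold_frac
  above <- which(!(vals < thr))
  horizon <- times[length(times)]
  if (length(above) == 0) {
    out <- list(value = times[1], converged = TRUE)
  } else if (above[length(above)] == length(vals)) {
    out <- list(value = NA_real_, converged = FALSE)
  } else {
    out <- list(value = times[above[length(above)] + 1], converged = TRUE)
  }
  structure(c(out, list(horizon = horizon,
                        criterion = sprintf("persistent drop below %.4g of initial loss",
                                            threshold_frac))),
            class = "coopnet_response_time")
}

#' @export
print.coopnet_response_time <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Response time: %g (horizon %g; %s)\n", x$value, x$horizon,
                x$criterion))
  else cat(sprintf("Response time: not converged within horizon %g\n", x$horizon))
  invisible(x)
}

#' Analytic response time of a circulant excitatory network
#'
#' For a purely excitatory circulant recurrent matrix with summed recurrent
#' weight `w_sum_rec` per neuron, the loss decays with time constant
#' `tau_resp = tau / (1 - w_sum_rec)`; the largest network eigenvalue equals
#' `w_sum_rec`.
#'
#' @param w_sum_rec summed recurrent weight per neuron, in `[0, 1)`.
#' @param tau membrane time constant.
#' @return Response time (same units as `tau`).
#' @export
analytic_response_time <- function(w_sum_rec, tau = 1) {
  if (any(w_sum_rec < 0)) stop_param("w_sum_rec must be non-negative")
  if (any(w_sum_rec >= 1))
    stop_param("w_sum_rec >= 1: network unstable, no finite response time")
  tau / (1 - w_sum_rec)
}

#' Response-time approximations in terms of the RF width
#'
#' Evaluates the response time of the cooperative nearest-neighbour ring as a
#' function of the RF width `d`: the exact circulant expression
#' `tau / (1 - 2 w_rec(d))` and the large-`d` expansions `(1 + 2 d^2) tau`
#' and `n_rf^2 tau / 2`.
#'
#' @param d RF width parameter.
#' @param tau membrane time constant.
#' @return A list with `exact`, `quadratic` (`(1 + 2 d^2) tau`), and
#'   `large_d` (`n_rf^2 / 2 * tau`).
#' @export
approx_response_time <- function(d, tau = 1) {
  w <- cooperative_weights(d)
  list(exact = tau / (1 - 2 * w$w_rec),
       quadratic = (1 + 2 * d^2) * tau,
       large_d = (2 * d + 1)^2 / 2 * tau)
}

#' Eigenvalues of a circulant matrix
#'
#' Computes the full eigenvalue sequence of a circulant matrix through the
#' discrete Fourier transform of its first row. For the non-negative
#' symmetric matrices used here the largest eigenvalue equals the row sum.
#'
#' @param W a circulant matrix (dense or sparse).
#' @param tol tolerance for the circulant-structure check.
#' @return Numeric (or complex, if the matrix is not symmetric) eigenvalues.
#' @export
circulant_spectrum <- function(W, tol = 1e-10) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (n != ncol(W)) stop_param("W must be square")
  first <- W[1, ]
  for (i in seq_len(n)[-1]) {
    shifted <- first[((seq_len(n) - i) %% n) + 1]
    if (max(abs(W[i, ] - shifted)) > tol)
      stop_param("W is not circulant (row ", i, " deviates)")
  }
  ev <- fft(first)
  if (max(abs(Im(ev))) < 1e-9 * max(1, max(abs(Re(ev))))) ev <- Re(ev)
  ev
}

#' Summed recurrent weight realizing a target RF size
#'
#' Inverts the RF-size relation of the 1D cooperative ring: for a target size
#' `n_rf`, the width is `d = (n_rf - 1) / 2`, `gamma = exp(-1/d)` and the
#' summed nearest-neighbour weight is `w_sum = 2 gamma / (1 + gamma^2)`.
#'
#' @param n_rf target RF size (> 1).
#' @return Summed recurrent weight in `(0, 1)`.
#' @export
wsum_for_rf_size <- function(n_rf) {
  if (any(n_rf <= 1)) stop_param("n_rf must exceed 1")
  d <- (n_rf - 1) / 2
  g <- exp(-1 / d)
  2 * g / (1 + g^2)
}

#' Fast simulation of the cooperative ring
#'
#' Compiled midpoint/Euler integration of the nearest-neighbour ring
#' `tau dx/dt = -x + w_rec (x_{i+1} + x_{i-1}) + h_i` under a constant drive
#' `h`, returning the L1 loss against the steady state at every step.
#'
#' @param w_rec recurrent weight per nearest-neighbour synapse.
#' @param h constant external drive vector (`W_ff %*% r`).
#' @param N number of neurons (defaults to `length(h)`).
#' @param x0 initial state (default zero).
#' @param dt step size, `T` horizon (units of `tau`).
#' @param T integration horizon.
#' @param tau membrane time constant.
#' @param method `"midpoint"` (default) or `"euler"`.
#' @param x_target loss target; defaults to the exact circulant steady state.
#' @param record_stride if positive, also store every
#'   `record_stride`-th state.
#' @return A list with `loss` (a `coopnet_loss`), `x_final`, `x_target`,
#'   `diverged`, and (optionally) a `coopnet_trajectory` in `trajectory`.
#' @export
simulate_ring <- function(w_rec, h, N = length(h), x0 = NULL, dt = 0.01, T,
                          tau = 1, method = c("midpoint", "euler"),
                          x_target = NULL, record_stride = 0) {
  method <- match.arg(method)
  if (anyNA(h)) stop_param("NaN in drive")
  x0 <- x0 %||% numeric(N)
  x_target <- x_target %||% ring_steady_fft(w_rec, h)
  n_steps <- round(T / dt)
  res <- ring_rate_sim_cpp(x0, h, w_rec, tau, dt, n_steps,
                           method == "midpoint", x_target,
                           as.integer(record_stride))
  out <- list(loss = new_loss_curve((0:n_steps) * dt, res$loss, res$diverged),
              x_final = res$x_final, x_target = x_target,
              diverged = res$diverged)
  if (record_stride > 0) {
    keep <- seq(0, n_steps, by = record_stride)
    out$trajectory <- new_trajectory(keep * dt, t(res$states), dt, method,
                                     res$diverged)
  }
  out
}
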