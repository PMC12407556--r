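#' Balanced (delayed-inhibition) ring specification
#'
#' Cooperative ring in which each recurrent excitatory synapse is paired with
#' an equally strong, delayed inhibitory one. With inhibitory activity
#' mirroring excitatory activity after a lag `tau_lag`, the dynamics can be
#' written in terms of net weights `w_rec_net` (defining the RF) and balanced
#' weights `w_rec_bal` (acting only on activity changes
#' `Delta x_i(t) = x_i(t) - x_i(t - tau_lag)`):
#' `tau dx/dt = -x + w_net (x_{i+1}+x_{i-1}) + w_bal (Dx_{i+1}+Dx_{i-1})
#'  + w_ff r`.
#' The underlying excitatory and inhibitory weights are recoverable as
#' `w_rec_E = w_net + w_bal` and `w_rec_I = -w_bal`.
#'
#' @param d RF width (sets `w_rec_net` and `w_ff` to the cooperative values);
#'   alternatively give `w_net` directly.
#' @param w_bal balanced weight per synapse (>= 0).
#' @param tau_lag excitation-inhibition lag (default 0.1 tau).
#' @param N ring size.
#' @param tau membrane time constant.
#' @param w_net net weight per synapse (overrides `d` if given).
#' @param w_ff feedforward weight (default `1 - 2 w_net`, preserving unit
#'   response gain).
#' @return An object of class `balanced_spec`.
#' @export
balanced_spec <- function(d = NULL, w_bal, tau_lag = 0.1, N = 200, tau = 1,
                          w_net = NULL, w_ff = NULL) {
  if (is.null(w_net)) {
    if (is.null(d)) stop_param("give either d or w_net")
    cw <- cooperative_weights(d)
    w_net <- cw$w_rec
    w_ff <- w_ff %||% cw$w_ff
  }
  w_ff <- w_ff %||% (1 - 2 * w_net)
  if (w_bal < 0) stop_param("w_bal must be >= 0")
  if (tau_lag <= 0) stop_param("tau_lag must be > 0")
  structure(list(N = as.integer(N), tau = tau, tau_lag = tau_lag, d = d,
                 w_net = w_net, w_bal = w_bal, w_ff = w_ff,
                 w_rec_E = w_net + w_bal, w_rec_I = -w_bal),
            class = "balanced_spec")
}

#' @export
print.balanced_spec <- function(x, ...) {
  cat(sprintf(
    "Balanced ring: N = %d, w_net = %.4f, w_bal = %.4f, tau_lag = %g (E: %.4f, I: %.4f)\n",
    x$N, x$w_net, x$w_bal, x$tau_lag, x$w_rec_E, x$w_rec_I))
  invisible(x)
}

#' Integrate the balanced ring (midpoint with delay)
#'
#' Midpoint integration of the delay differential dynamics; delayed midpoint
#' values are copies of the non-delayed midpoint values `tau_lag` earlier,
#' and the history is `x(t) = x0` for `t <= 0`. `tau_lag` must be an integer
#' multiple of `dt`.
#'
#' @param spec a [balanced_spec()].
#' @param r constant input vector.
#' @param x0 initial (and historic) state, default zero.
#' @param dt step size; `T` horizon.
#' @param T integration horizon.
#' @param record_stride if positive, record every that-many-th state.
#' @return As [simulate_ring()]: list with `loss`, `x_final`, `x_target`,
#'   `diverged`, optionally `trajectory`.
#' @export
delayed_integrate <- function(spec, r, x0 = NULL, dt = 0.01, T,
                              record_stride = 0) {
  if (!inherits(spec, "balanced_spec")) stop_param("spec must be a balanced_spec")
  N <- spec$N
  if (length(r) != N) stop_param("input length must equal N")
  lag_steps <- spec$tau_lag / dt
  if (abs(lag_steps - round(lag_steps)) > 1e-8)
    stop_param("tau_lag must be an integer multiple of dt")
  lag_steps <- as.integer(round(lag_steps))
  x0 <- x0 %||% numeric(N)
  h <- spec$w_ff * r
  x_target <- ring_steady_fft(spec$w_net, h)
  n_steps <- round(T / dt)
  res <- ring_delay_sim_cpp(x0, h, spec$w_net, spec$w_bal, spec$tau, dt,
                            lag_steps, n_steps, x_target,
                            as.integer(record_stride))
  out <- list(loss = new_loss_curve((0:n_steps) * dt, res$loss, res$diverged),
              x_final = res$x_final, x_target = x_target,
              diverged = res$diverged)
  if (record_stride > 0) {
    keep <- seq(0, n_steps, by = record_stride)
    out$trajectory <- new_trajectory(keep * dt, t(res$states), dt,
                                     "midpoint+delay", res$diverged)
  }
  out
}

# Scalar characteristic function of the uniform (sum) mode of the delay
# system: f(s) = tau s + 1 - w_sum_net - w_sum_bal (1 - exp(-s tau_lag)).
char_fun <- function(s, w_sum_net, w_sum_bal, tau_lag, tau) {
  tau * s + 1 - w_sum_net - w_sum_bal * (1 - exp(-s * tau_lag))
}

#' Dominant characteristic roots of the balanced delay dynamics
#'
#' The uniform (sum) mode of the balanced ring, which governs the linearized
#' L1 loss, obeys the scalar transcendental characteristic equation
#' `tau s = -1 + w_sum_net + w_sum_bal (1 - exp(-s tau_lag))`. Roots are
#' located by complex Newton iteration from a grid of real and imaginary
#' starting points; the dominant (largest real part) roots determine the
#' decay rate `lambda = -Re(s)` and oscillation frequency `omega = |Im(s)|`
#' of the loss.
#'
#' @param w_sum_net summed net weight (e.g. `2 w_net` for the ring).
#' @param w_sum_bal summed balanced weight.
#' @param tau_lag excitation-inhibition lag.
#' @param tau membrane time constant.
#' @param n_freq number of imaginary-axis starting points.
#' @return A list with `roots` (complex, sorted by decreasing real part),
#'   `lambda` (decay rate of the dominant root), `omega` (its frequency) and
#'   `regime` (`"overdamped"`, `"critical"`, or `"underdamped"`).
#' @export
characteristic_roots <- function(w_sum_net, w_sum_bal, tau_lag, tau = 1,
                                 n_freq = 8) {
  if (!all(is.finite(c(w_sum_net, w_sum_bal, tau_lag, tau))))
    stop_param("parameters must be finite")
  f <- function(s) char_fun(s, w_sum_net, w_sum_bal, tau_lag, tau)
  fp <- function(s) tau - w_sum_bal * tau_lag * exp(-s * tau_lag)
  starts <- c((w_sum_net + w_sum_bal - 1) / tau + 0i,
              -(1 - w_sum_net) / tau + 0i,
              complex(real = 0, imaginary = pi * (seq_len(n_freq) - 0.5) / tau_lag),
              complex(real = -1 / tau_lag, imaginary = pi * (seq_len(n_freq) - 0.5) / tau_lag))
  roots <- complex(0)
  for (s0 in starts) {
    s <- s0
    ok <- FALSE
    for (it in 1:100) {
      d <- f(s) / fp(s)
      if (!is.finite(Mod(d))) break
      s <- s - d
      if (Mod(d) < 1e-13 * max(1, Mod(s))) { ok <- TRUE; break }
    }
    if (ok && Mod(f(s)) < 1e-9) roots <- c(roots, s)
  }
  if (length(roots) == 0) stop("characteristic root finder did not converge")
  # deduplicate and keep conjugate representatives with Im >= 0
  roots <- roots[Im(roots) > -1e-10]
  roots[abs(Im(roots)) < 1e-10] <- Re(roots[abs(Im(roots)) < 1e-10])
  ord <- order(-Re(roots), Im(roots))
  roots <- roots[ord]
  keep <- rep(TRUE, length(roots))
  if (length(roots) > 1) for (i in 2:length(roots))
    if (any(Mod(roots[i] - roots[seq_len(i - 1)]) < 1e-7 * max(1, Mod(roots[i]))))
      keep[i] <- FALSE
  roots <- roots[keep]
  dom <- roots[1]
  wc <- tryCatch(find_critical_balance(w_sum_net, tau_lag, tau),
                 error = function(e) NA_real_)
  regime <- if (is.na(wc)) NA_character_
            else if (w_sum_bal < wc * (1 - 1e-9)) "overdamped"
            else if (w_sum_bal > wc * (1 + 1e-9)) "underdamped"
            else "critical"
  list(roots = roots, lambda = -Re(dom), omega = abs(Im(dom)), regime = regime)
}

#' Critical balance strength
#'
#' The balanced weight at which the two dominant real roots of the sum-mode
#' characteristic equation coalesce ("critical damping"), maximizing the loss
#' decay rate. At the double root, `f(s) = f'(s) = 0`; eliminating `s` gives
#' a scalar condition solved by bisection.
#'
#' @inheritParams characteristic_roots
#' @return The critical summed balanced weight `w_sum_bal_c`.
#' @export
find_critical_balance <- function(w_sum_net, tau_lag, tau = 1) {
  if (w_sum_net < 0 || w_sum_net >= 1) stop_param("need 0 <= w_sum_net < 1")
  # f'(s) = 0 at s* = -log(tau / (w_bal tau_lag)) / tau_lag; substituting
  # into f gives a monotone function of w_bal bracketed by the instability
  # threshold.
  g <- function(wb) {
    sstar <- -log(tau / (wb * tau_lag)) / tau_lag
    tau * sstar + 1 - w_sum_net - wb + tau / tau_lag
  }
  upper <- find_instability_threshold(w_sum_net, tau_lag, tau)
  lo <- tau / tau_lag * 1e-8
  if (g(lo) > 0 || g(upper) < 0) stop("failed to bracket the critical balance")
  uniroot(g, c(lo, upper), tol = 1e-12)$root
}

#' Instability threshold of the balanced ring
#'
#' The summed balanced weight at which the dominant characteristic root
#' crosses the imaginary axis and the delay dynamics diverge. At the
#' crossing, `s = i omega` with
#' `omega tau = (1 - w_sum_net) sin(omega tau_lag) / (1 - cos(omega tau_lag))`
#' and `w_sum_bal = (1 - w_sum_net) / (1 - cos(omega tau_lag))`. The scaled
#' threshold `(tau_lag / tau) w_sum_bal` is slightly larger than 1.
#'
#' @inheritParams characteristic_roots
#' @return The summed balanced weight at the onset of divergence.
#' @export
find_instability_threshold <- function(w_sum_net, tau_lag, tau = 1) {
  if (w_sum_net < 0 || w_sum_net >= 1) stop_param("need 0 <= w_sum_net < 1")
  f <- function(om) om * tau - (1 - w_sum_net) * sin(om * tau_lag) /
    (1 - cos(om * tau_lag))
  om <- uniroot(f, c(1e-9 / tau_lag, (2 - 1e-9) * pi / tau_lag * 0.5),
                tol = 1e-14)$root
  (1 - w_sum_net) / (1 - cos(om * tau_lag))
}

#' Regime diagram of the balanced delay dynamics
#'
#' Tabulates the decay rate `lambda` and oscillation frequency `omega` of the
#' dominant characteristic root over a range of balance strengths, on the
#' scaled axis `(tau_lag / tau) * w_sum_bal`. The table spans the overdamped,
#' critical, underdamped and divergent regimes and can be written to CSV for
#' plotting.
#'
#' @inheritParams characteristic_roots
#' @param scaled_balance grid of scaled balance strengths
#'   `(tau_lag / tau) * w_sum_bal` (default: 60 points from 0 to 10 percent
#'   beyond the instability threshold).
#' @return A data frame with columns `scaled_balance`, `w_sum_bal`,
#'   `lambda`, `omega`, and `regime`.
#' @export
balance_regime_table <- function(w_sum_net, tau_lag, tau = 1,
                                 scaled_balance = NULL) {
  thr <- find_instability_threshold(w_sum_net, tau_lag, tau)
  scaled_balance <- scaled_balance %||%
    seq(0, 1.1 * tau_lag / tau * thr, length.out = 60)
  rows <- lapply(scaled_balance, function(sb) {
    wb <- sb * tau / tau_lag
    cr <- characteristic_roots(w_sum_net, wb, tau_lag, tau)
    data.frame(scaled_balance = sb, w_sum_bal = wb,
               lambda = cr$lambda, omega = cr$omega, regime = cr$regime)
  })
  do.call(rbind, rows)
}

#' Closed-form response time at critical balance
#'
#' Predicted response time of a critically balanced network: approximately
#' the geometric mean `sqrt(tau_resp * tau_lag / 2)` of the unbalanced
#' response time and the lag. In terms of RF size this gives
#' `n_rf/2 * sqrt(tau tau_lag)` for the 1D ring and
#' `n_rf_ms/(2 sqrt(2)) * sqrt(tau tau_lag)` for the mixed-selectivity grid
#' (whose effective time constant is doubled but whose RF size doubles too).
#'
#' @param n_rf RF size (`n_rf_ms = 2(2d+1)` for the MS variant).
#' @param tau membrane time constant.
#' @param tau_lag excitation-inhibition lag.
#' @param variant `"1d"` or `"ms"`.
#' @return Predicted response time.
#' @export
predicted_balanced_response_time <- function(n_rf, tau = 1, tau_lag = 0.1,
                                             variant = c("1d", "ms")) {
  variant <- match.arg(variant)
  switch(variant,
         "1d" = n_rf / 2 * sqrt(tau * tau_lag),
         "ms" = n_rf / (2 * sqrt(2)) * sqrt(tau * tau_lag))
}
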