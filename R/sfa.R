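#' Spike-frequency-adaptation network specification
#'
#' Cooperative ring with spike-frequency adaptation (SFA). Each neuron
#' carries an adaptation current `u_i` that relaxes towards its activity,
#' `tau_sfa du/dt = -u + x`, and feeds back as `-a_sfa * u` onto the rate
#' equation. To keep the stationary state identical to the network without
#' adaptation, the recurrent and feedforward weights are scaled up by
#' `1 + a_sfa`:
#' `tau dx/dt = -x + (1+a_sfa) w_rec (x_{i+1}+x_{i-1}) + (1+a_sfa) w_ff r
#'  - a_sfa u`.
#'
#' @param d RF width of the underlying cooperative ring.
#' @param a_sfa adaptation strength (>= 0).
#' @param tau_sfa adaptation time constant (> 0).
#' @param N ring size.
#' @param tau membrane time constant.
#' @return An object of class `sfa_spec`.
#' @export
sfa_spec <- function(d, a_sfa, tau_sfa = 1, N = 200, tau = 1) {
  if (a_sfa < 0) stop_param("a_sfa must be >= 0")
  if (tau_sfa <= 0) stop_param("tau_sfa must be > 0")
  w <- cooperative_weights(d)
  structure(list(N = as.integer(N), d = d, tau = tau,
                 a_sfa = a_sfa, tau_sfa = tau_sfa,
                 w_rec = w$w_rec, w_ff = w$w_ff,
                 w_rec_eff = (1 + a_sfa) * w$w_rec,
                 w_ff_eff = (1 + a_sfa) * w$w_ff),
            class = "sfa_spec")
}

#' @export
print.sfa_spec <- function(x, ...) {
  cat(sprintf(
    "SFA ring: N = %d, d = %g, a_sfa = %g, tau_sfa = %g (eff. w_rec = %.4f)\n",
    x$N, x$d, x$a_sfa, x$tau_sfa, x$w_rec_eff))
  invisible(x)
}

#' Integrate the SFA ring (Euler)
#'
#' Joint Euler integration of activities and adaptation currents. The
#' stationary state satisfies `u = x` and equals the steady state of the
#' network without adaptation, independent of `a_sfa` and `tau_sfa`.
#'
#' @param spec an [sfa_spec()].
#' @param r constant input vector (length `N`).
#' @param x0,u0 initial activity and adaptation (default zero).
#' @param dt Euler step (default 0.01 tau).
#' @param T horizon.
#' @param record_stride if positive, record every that-many-th `(x, u)` state.
#' @return A list with `loss` (L1 loss against the adaptation-free steady
#'   state), `mean_norm_loss` (time-averaged loss normalized by `|x*|_1`),
#'   `x_final`, `u_final`, `x_target`, `diverged`, optionally `trajectory`
#'   (states columns: `N` activities then `N` adaptation currents).
#' @export
sfa_integrate <- function(spec, r, x0 = NULL, u0 = NULL, dt = 0.01, T = 500,
                          record_stride = 0) {
  if (!inherits(spec, "sfa_spec")) stop_param("spec must be an sfa_spec")
  N <- spec$N
  if (length(r) != N) stop_param("input length must equal N")
  x0 <- x0 %||% numeric(N)
  u0 <- u0 %||% numeric(N)
  h <- spec$w_ff_eff * r
  x_target <- ring_steady_fft(spec$w_rec, spec$w_ff * r)
  n_steps <- round(T / dt)
  res <- ring_sfa_sim_cpp(x0, u0, h, spec$w_rec_eff, spec$a_sfa, spec$tau,
                          spec$tau_sfa, dt, n_steps, x_target,
                          as.integer(record_stride))
  out <- list(loss = new_loss_curve((0:n_steps) * dt, res$loss, res$diverged),
              mean_norm_loss = res$mean_norm_loss,
              x_final = res$x_final, u_final = res$u_final,
              x_target = x_target, diverged = res$diverged)
  if (record_stride > 0) {
    keep <- seq(0, n_steps, by = record_stride)
    out$trajectory <- new_trajectory(keep * dt, t(res$states), dt, "euler",
                                     res$diverged)
  }
  out
}

#' Optimize the adaptation strength
#'
#' Linear grid search for the adaptation strength `a_sfa` minimizing the
#' time-averaged normalized L1 loss `(1/T) int_0^T |x(t) - x*|_1 / |x*|_1 dt`
#' of the trial protocol (zero initialization, constant unit input at one
#' site, horizon `T`). Diverging grid points receive an infinite loss. An
#' optional refinement pass repeats the search on a finer grid around the
#' coarse optimum.
#'
#' @param d RF width.
#' @param tau_sfa adaptation time constant (default: equal to `tau`).
#' @param grid vector of candidate `a_sfa` values.
#' @param T trial length (default 500 tau).
#' @param N ring size, `tau` membrane constant, `dt` Euler step.
#' @param tau membrane time constant.
#' @param dt Euler step size.
#' @param j0 stimulated input neuron.
#' @param refine_passes number of successive grid refinements around the
#'   running optimum; each pass spans one previous step on either side with a
#'   quarter of the previous spacing. The integrated loss is sharply peaked
#'   just below the stability boundary of the effective sum mode, so a single
#'   coarse grid can straddle the interior minimum.
#' @return A list with `a_opt`, `loss_opt`, and `table`
#'   (a data frame of all evaluated `a_sfa` / mean-loss pairs).
#' @export
optimize_asfa <- function(d, tau_sfa = tau, grid = seq(0, 20, length.out = 41),
                          T = 500, N = 200, tau = 1, dt = 0.01, j0 = N %/% 2,
                          refine_passes = 3) {
  if (length(grid) == 0) stop_param("grid must be nonempty")
  r <- numeric(N); r[j0] <- 1
  eval_a <- function(a) {
    sp <- sfa_spec(d, a, tau_sfa = tau_sfa, N = N, tau = tau)
    sfa_integrate(sp, r, dt = dt, T = T)$mean_norm_loss
  }
  losses <- vapply(grid, eval_a, numeric(1))
  tab <- data.frame(a_sfa = grid, mean_norm_loss = losses, pass = "coarse")
  if (all(!is.finite(losses))) stop_param("all grid points diverged")
  best <- which.min(losses)
  a_opt <- grid[best]; loss_opt <- losses[best]
  step <- if (length(grid) > 1) {
    if (best == 1) grid[2] - grid[1] else grid[best] - grid[best - 1]
  } else 0
  if (step > 0) for (pass in seq_len(refine_passes)) {
    fine <- seq(max(0, a_opt - step), a_opt + step, by = step / 4)
    fine <- setdiff(round(fine, 12), round(tab$a_sfa, 12))
    if (length(fine)) {
      fl <- vapply(fine, eval_a, numeric(1))
      tab <- rbind(tab, data.frame(a_sfa = fine, mean_norm_loss = fl,
                                   pass = paste0("refine", pass)))
      if (min(fl, na.rm = TRUE) < loss_opt) {
        a_opt <- fine[which.min(fl)]
        loss_opt <- min(fl, na.rm = TRUE)
      }
    }
    step <- step / 4
  }
  list(a_opt = a_opt, loss_opt = loss_opt, table = tab)
}

#' Effective two-variable mode analysis of the SFA ring
#'
#' Reduces the SFA network to the dynamics of the uniform (sum) mode, a
#' two-variable linear system in `(x, u)` with matrix
#' `[[ (2 (1+a) w_rec - 1)/tau, -a/tau ], [ 1/tau_sfa, -1/tau_sfa ]]`,
#' and reports its eigenvalues, complex Schur form, and the magnitude of the
#' Schur off-diagonal coupling. A strong off-diagonal coupling from the
#' difference mode (activity ahead of adaptation) to the sum mode is the
#' signature of balanced amplification; complex eigenvalues flag oscillatory
#' modes.
#'
#' @param spec an [sfa_spec()].
#' @return A list with `matrix`, `eigenvalues`, `schur_T`, `coupling`
#'   (`|T[1,2]|`), and `oscillatory`.
#' @export
effective_mode_analysis <- function(spec) {
  if (!inherits(spec, "sfa_spec")) stop_param("spec must be an sfa_spec")
  M <- matrix(c((2 * spec$w_rec_eff - 1) / spec$tau, 1 / spec$tau_sfa,
                -spec$a_sfa / spec$tau, -1 / spec$tau_sfa), 2, 2)
  ev <- eigen(M)
  lam <- ev$values
  # complex Schur form: unitary Q = [q1, q2] with q1 an eigenvector
  q1 <- ev$vectors[, 1]
  q1 <- q1 / sqrt(sum(Mod(q1)^2))
  q2 <- c(-Conj(q1[2]), Conj(q1[1]))
  Q <- cbind(q1, q2)
  Tm <- Conj(t(Q)) %*% M %*% Q
  list(matrix = M, eigenvalues = lam, schur_T = Tm,
       coupling = Mod(Tm[1, 2]),
       oscillatory = any(abs(Im(lam)) > 1e-12))
}
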