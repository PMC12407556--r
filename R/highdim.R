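#' Mixed-selectivity grid weights
#'
#' Weights of the linear mixed-selectivity (MS) network on an `N x N` grid,
#' where each neuron responds to two stimuli with the 1D exponential profile
#' along each grid axis: `w_rec_ms = w_rec / (1 + 2 w_rec) = gamma/(1+gamma)^2`
#' and `w_ff_ms = w_ff / (1 + 2 w_rec) = (1-gamma)/(1+gamma)`. The factor
#' `a = (1 - 2 w_rec_ms)^{-1} = 1 + 2 w_rec` maps the MS dynamics onto the 1D
#' ring with enlarged time constant `a tau`.
#'
#' @param d RF width along one axis.
#' @return List with `w_rec_ms`, `w_ff_ms`, `a`, `gamma`, and the nominal MS
#'   RF size `n_rf_ms = 2 (2 d + 1)`.
#' @export
ms_weights <- function(d) {
  cw <- cooperative_weights(d)
  a <- 1 + 2 * cw$w_rec
  list(w_rec_ms = cw$w_rec / (1 + 2 * cw$w_rec),
       w_ff_ms = cw$w_ff / (1 + 2 * cw$w_rec),
       a = a, gamma = cw$gamma, n_rf_ms = 2 * (2 * d + 1))
}

# Sparse four-neighbour adjacency of an nx-by-ny torus (column-major).
torus_adjacency <- function(nx, ny) {
  n <- nx * ny
  id <- matrix(seq_len(n), nx, ny)
  right <- id[c(2:nx, 1), , drop = FALSE]
  left <- id[c(nx, seq_len(nx - 1)), , drop = FALSE]
  up <- id[, c(2:ny, 1), drop = FALSE]
  down <- id[, c(ny, seq_len(ny - 1)), drop = FALSE]
  Matrix::sparseMatrix(i = rep(as.vector(id), 4),
                       j = c(as.vector(right), as.vector(left),
                             as.vector(up), as.vector(down)),
                       x = 1, dims = c(n, n))
}

#' Mixed-selectivity grid network
#'
#' Builds the `N^2`-neuron MS network as a `coopnet_network`: four recurrent
#' nearest-neighbour synapses of strength `w_rec_ms` per neuron, and two
#' feedforward synapses per neuron mapping the two `N`-dimensional inputs
#' `(r1, r2)` onto the grid, `h_ij = w_ff_ms (r1_i + r2_j)`. Inputs to
#' [steady_state()] etc. are the concatenation `c(r1, r2)`.
#'
#' @param N grid side length.
#' @param d RF width along one axis.
#' @param tau membrane time constant.
#' @return A `coopnet_network` with `topology = "ms2d"`.
#' @export
ms_network <- function(N, d, tau = 1) {
  w <- ms_weights(d)
  n <- N * N
  A <- torus_adjacency(N, N) * w$w_rec_ms
  ij <- expand.grid(i = seq_len(N), j = seq_len(N))
  W_ff <- Matrix::sparseMatrix(i = rep(seq_len(n), 2),
                               j = c(ij$i, N + ij$j),
                               x = w$w_ff_ms, dims = c(n, 2 * N))
  network_spec(A, W_ff, tau = tau, topology = "ms2d",
               info = c(w, list(N_axis = N, d = d)))
}

#' Torus network for a two-dimensional stimulus
#'
#' Both input and feature neurons live on an `N x N` torus; each feature
#' neuron receives one feedforward synapse and four recurrent ones. The RF is
#' approximately radially symmetric,
#' `RF(rho) ~ c K0(gamma2d rho)` with
#' `gamma2d = sqrt((1 - 4 w_rec_2d) / w_rec_2d)` and
#' `c = w_ff_2d / (2 pi w_rec_2d)`.
#'
#' @param N grid side length.
#' @param w_rec_2d recurrent weight per synapse (`< 0.25` for stability).
#' @param w_ff_2d feedforward weight (default `1 - 4 w_rec_2d`, unit gain for
#'   uniform input).
#' @param tau membrane time constant.
#' @return A `coopnet_network` with `topology = "torus2d"`.
#' @export
torus2d_network <- function(N, w_rec_2d, w_ff_2d = 1 - 4 * w_rec_2d, tau = 1) {
  if (w_rec_2d < 0) stop_param("w_rec_2d must be non-negative")
  A <- torus_adjacency(N, N) * w_rec_2d
  network_spec(A, Matrix::Diagonal(N * N, w_ff_2d), tau = tau,
               topology = "torus2d",
               info = list(N_axis = N, w_rec_2d = w_rec_2d, w_ff_2d = w_ff_2d,
                           gamma_2d = if (w_rec_2d > 0)
                             sqrt(max(0, 1 - 4 * w_rec_2d) / w_rec_2d) else Inf,
                           c_amp = if (w_rec_2d > 0)
                             w_ff_2d / (2 * pi * w_rec_2d) else NA_real_))
}

#' Stationary response of the 2D-stimulus network
#'
#' Linear solve `x = (1 - W_rec)^{-1} W_ff r` on the torus; errors when
#' `4 w_rec_2d >= 1`.
#'
#' @param net a `coopnet_network` from [torus2d_network()].
#' @param r input, as an `N x N` matrix or a vector of length `N^2`
#'   (column-major).
#' @return Steady-state activity as an `N x N` matrix.
#' @export
torus2d_steady <- function(net, r) {
  if (!identical(net$topology, "torus2d")) stop_param("net must be a torus2d network")
  if (4 * net$info$w_rec_2d >= 1)
    stop_param("4 w_rec_2d >= 1: network unstable")
  N <- net$info$N_axis
  x <- steady_state(net, as.vector(r))
  matrix(x, N, N)
}

#' Measured RF size by cumulative coverage
#'
#' The number of largest response entries (sorted in decreasing order)
#' whose cumulative sum first reaches a fraction `1 - exp(-1)` (about 63%) of
#' the total summed response. For the continuous 1D exponential RF this
#' convention recovers the coverage of the interval within one width `d` of
#' the centre; for measured 2D profiles it generalizes the feedforward
#' synapse count `n_rf`.
#'
#' @param profile non-negative response profile (vector or matrix).
#' @param dim dimensionality tag (1 or 2; informational).
#' @param frac coverage fraction (default `1 - exp(-1)`).
#' @return Integer count `n_rf_hat`.
#' @export
measure_rf_size <- function(profile, dim = 1, frac = 1 - exp(-1)) {
  p <- as.vector(profile)
  if (any(p < -1e-12 * max(abs(p)))) p <- pmax(p, 0)
  tot <- sum(p)
  if (tot <= 0) stop_param("profile must have positive total mass")
  cs <- cumsum(sort(p, decreasing = TRUE))
  as.integer(which(cs >= frac * tot)[1])
}

#' Equivalence of the MS grid and the 1D ring
#'
#' Simulates the full MS grid with an input along stimulus axis 1 only and
#' compares against the 1D cooperative ring with time constant `a tau`. For
#' homogeneous initial conditions the grid activity is constant along the
#' second axis and the two trajectories agree to integrator tolerance.
#'
#' @param d RF width; `N` grid side.
#' @param N grid side length.
#' @param j0 stimulated value of stimulus 1.
#' @param T,dt simulation horizon and step.
#' @param tau membrane time constant.
#' @return List with `max_dev` (maximum absolute deviation between the grid
#'   and ring trajectories over recorded times), `column_spread` (maximum
#'   deviation from column-constancy), and the two final states.
#' @export
ms_to_1d_check <- function(d, N = 64, j0 = N %/% 2, T = 20, dt = 0.01,
                           tau = 1) {
  w <- ms_weights(d)
  r1 <- numeric(N); r1[j0] <- 1
  h2d <- w$w_ff_ms * rep(r1, times = N)     # h_ij = w_ff_ms r1_i, all j
  n <- N * N
  stride <- max(1L, round(1 / dt))
  res2d <- torus_sim_cpp(numeric(n), h2d, N, N, w$w_rec_ms, 0, tau, dt, 0L,
                         round(T / dt), numeric(n), stride)
  cw <- cooperative_weights(d)
  res1d <- ring_rate_sim_cpp(numeric(N), w$w_ff_ms * r1 * w$a, cw$w_rec,
                             w$a * tau, dt, round(T / dt), TRUE, numeric(N),
                             stride)
  S2 <- res2d$states
  S1 <- res1d$states
  # grid states: column-major (i + N (j-1)); compare each column with 1D
  max_dev <- 0; spread <- 0
  for (k in seq_len(ncol(S2))) {
    G <- matrix(S2[, k], N, N)
    spread <- max(spread, max(abs(G - G[, 1])))
    max_dev <- max(max_dev, max(abs(G[, 1] - S1[, k])))
  }
  list(max_dev = max_dev, column_spread = spread,
       final_grid = matrix(S2[, ncol(S2)], N, N), final_ring = S1[, ncol(S1)])
}

#' Fast torus simulation
#'
#' Compiled midpoint integration of the four-neighbour torus under constant
#' drive, optionally with delayed balancing inhibition
#' (`w_bal > 0`, `tau_lag > 0`).
#'
#' @param w_rec recurrent weight per synapse; `w_bal` balanced weight per
#'   synapse.
#' @param h constant drive vector of length `nx * ny` (column-major).
#' @param nx,ny grid dimensions.
#' @param w_bal balanced weight per synapse (0 disables the delay term).
#' @param tau_lag excitation-inhibition lag.
#' @param dt step; `T` horizon; `tau` membrane constant.
#' @param T integration horizon.
#' @param tau membrane time constant.
#' @param x_target loss target (default: exact steady state via the DFT).
#' @param x0 initial state.
#' @param record_stride optional state recording stride.
#' @return As [simulate_ring()].
#' @export
simulate_torus <- function(w_rec, h, nx, ny, w_bal = 0, tau_lag = 0.1,
                           dt = 0.01, T, tau = 1, x_target = NULL, x0 = NULL,
                           record_stride = 0) {
  x0 <- x0 %||% numeric(nx * ny)
  x_target <- x_target %||% torus_steady_fft(w_rec, h, nx, ny)
  lag_steps <- if (w_bal > 0) {
    ls <- tau_lag / dt
    if (abs(ls - round(ls)) > 1e-8)
      stop_param("tau_lag must be an integer multiple of dt")
    as.integer(round(ls))
  } else 0L
  n_steps <- round(T / dt)
  res <- torus_sim_cpp(x0, h, nx, ny, w_rec, w_bal, tau, dt, lag_steps,
                       n_steps, x_target, as.integer(record_stride))
  out <- list(loss = new_loss_curve((0:n_steps) * dt, res$loss, res$diverged),
              x_final = res$x_final, x_target = x_target,
              diverged = res$diverged)
  if (record_stride > 0) {
    keep <- seq(0, n_steps, by = record_stride)
    out$trajectory <- new_trajectory(keep * dt, t(res$states), dt, "midpoint",
                                     res$diverged)
  }
  out
}

#' Least-squares power-law fit
#'
#' Unweighted least squares of `log(y) ~ log(x)`, reporting the power-law
#' exponent and prefactor `y = prefactor * x^exponent`.
#'
#' @param x,y positive vectors.
#' @return List with `exponent`, `prefactor`, `r_squared`, and the `lm` fit.
#' @export
fit_power_law <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 2) stop_param("need at least two positive points")
  fit <- lm(log(y[ok]) ~ log(x[ok]))
  list(exponent = unname(coef(fit)[2]),
       prefactor = unname(exp(coef(fit)[1])),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       fit = fit)
}

#' Response-time scaling experiment
#'
#' Measures the response time as a function of RF size for a family of
#' cooperative-coding architectures and fits a power law. Families:
#' \describe{
#'   \item{`1d`}{purely excitatory ring; sizes are nominal `n_rf`,
#'     weights set via `gamma = exp(-1/d)`, `d = (n_rf - 1)/2`.}
#'   \item{`1d_sfa`}{ring with SFA; per size, `a_sfa` is grid-optimized
#'     (`tau_sfa = tau`) before the response time is measured.}
#'   \item{`1d_balanced`}{ring with delayed inhibition at the critical
#'     balance for each size.}
#'   \item{`ms`, `ms_balanced`}{mixed-selectivity grid; integrated through
#'     its exact 1D reduction (time constant `a tau`); sizes are
#'     `n_rf_ms = 2 n_rf`.}
#'   \item{`2d`, `2d_balanced`}{torus; sizes are driven by target response
#'     times (`w_sum = 1 - tau/tau_resp`) and the realized RF size
#'     `n_rf_hat` is measured from the converged profile.}
#' }
#' Diverged runs are excluded from the fit and reported.
#'
#' @param family one of `"1d"`, `"1d_sfa"`, `"1d_balanced"`, `"ms"`,
#'   `"ms_balanced"`, `"2d"`, `"2d_balanced"`.
#' @param sizes RF sizes (1D/MS families; default `seq(6, 50, 2)` nominal
#'   1D sizes).
#' @param tresp_targets target response times for the 2D families (default
#'   20 values log-spaced in `[10, 1000]`).
#' @param N ring size (1D families) or torus side (2D families).
#' @param tau membrane constant; `tau_lag` lag for balanced families.
#' @param tau_lag excitation-inhibition lag for balanced families.
#' @param dt integration step.
#' @param sfa_grid grid of `a_sfa` candidates for `1d_sfa`.
#' @param sfa_T trial length for the SFA loss optimization.
#' @param horizon_factor horizon as a multiple of the analytic (or
#'   predicted) response time.
#' @param verbose print progress.
#' @return An object of class `scaling_result`: list with `family`, `table`
#'   (size, measured response time, auxiliary columns), `fit` (power-law
#'   exponent/prefactor), and `excluded`.
#' @export
scaling_experiment <- function(family = c("1d", "1d_sfa", "1d_balanced",
                                          "ms", "ms_balanced",
                                          "2d", "2d_balanced"),
                               sizes = seq(6, 50, by = 2),
                               tresp_targets = 10^seq(1, 3, length.out = 20),
                               N = 200, tau = 1, tau_lag = 0.1, dt = 0.01,
                               sfa_grid = seq(0, 20, length.out = 41),
                               sfa_T = 500, horizon_factor = 5,
                               verbose = FALSE) {
  family <- match.arg(family)
  rows <- list()
  excluded <- list()
  j0 <- N %/% 2
  r <- numeric(N); r[j0] <- 1

  run_ring <- function(w_side, w_ff, eff_tau, horizon) {
    sim <- simulate_ring(w_side, w_ff * r, dt = dt, T = horizon, tau = eff_tau)
    if (sim$diverged) return(NULL)
    measure_response_time(sim$loss)
  }

  if (family %in% c("1d", "ms")) {
    a_fac <- 1
    for (n_rf in sizes) {
      d <- (n_rf - 1) / 2
      cw <- cooperative_weights(d)
      eff_tau <- if (family == "ms") (1 + 2 * cw$w_rec) * tau else tau
      t_ana <- analytic_response_time(2 * cw$w_rec, eff_tau)
      rt <- run_ring(cw$w_rec, cw$w_ff, eff_tau, horizon_factor * t_ana)
      size_out <- if (family == "ms") 2 * n_rf else n_rf
      if (is.null(rt) || !rt$converged) {
        excluded[[length(excluded) + 1]] <- size_out
      } else {
        rows[[length(rows) + 1]] <- data.frame(size = size_out, tresp = rt$value,
                                               tresp_analytic = t_ana)
      }
      if (verbose) message(family, " n_rf=", size_out)
    }
  } else if (family == "1d_sfa") {
    for (n_rf in sizes) {
      d <- (n_rf - 1) / 2
      opt <- optimize_asfa(d, tau_sfa = tau, grid = sfa_grid, T = sfa_T,
                           N = N, tau = tau, dt = dt, j0 = j0)
      sp <- sfa_spec(d, opt$a_opt, tau_sfa = tau, N = N, tau = tau)
      sim <- sfa_integrate(sp, r, dt = dt, T = sfa_T)
      rt <- measure_response_time(sim$loss)
      if (sim$diverged || !rt$converged) {
        excluded[[length(excluded) + 1]] <- n_rf
      } else {
        rows[[length(rows) + 1]] <- data.frame(size = n_rf, tresp = rt$value,
                                               a_sfa = opt$a_opt,
                                               mean_norm_loss = opt$loss_opt)
      }
      if (verbose) message("1d_sfa n_rf=", n_rf, " a*=", round(opt$a_opt, 2))
    }
  } else if (family %in% c("1d_balanced", "ms_balanced")) {
    for (n_rf in sizes) {
      d <- (n_rf - 1) / 2
      cw <- cooperative_weights(d)
      eff_tau <- if (family == "ms_balanced") (1 + 2 * cw$w_rec) * tau else tau
      wb_sum <- find_critical_balance(2 * cw$w_rec, tau_lag, eff_tau)
      spec <- balanced_spec(w_net = cw$w_rec, w_bal = wb_sum / 2,
                            tau_lag = tau_lag, N = N, tau = eff_tau,
                            w_ff = cw$w_ff)
      pred <- predicted_balanced_response_time(
        if (family == "ms_balanced") 2 * n_rf else n_rf, tau, tau_lag,
        if (family == "ms_balanced") "ms" else "1d")
      horizon <- max(30 * tau, 6 * horizon_factor * pred)
      sim <- delayed_integrate(spec, r, dt = dt, T = horizon)
      rt <- measure_response_time(sim$loss)
      size_out <- if (family == "ms_balanced") 2 * n_rf else n_rf
      if (sim$diverged || !rt$converged) {
        excluded[[length(excluded) + 1]] <- size_out
      } else {
        rows[[length(rows) + 1]] <- data.frame(size = size_out, tresp = rt$value,
                                               w_sum_bal = wb_sum,
                                               tresp_pred = pred)
      }
      if (verbose) message(family, " n_rf=", size_out)
    }
  } else { # 2d families
    balanced <- family == "2d_balanced"
    n <- N * N
    center <- (N %/% 2) + N * (N %/% 2 - 1)
    r2 <- numeric(n); r2[center] <- 1
    for (tt in tresp_targets) {
      w_sum <- 1 - tau / tt
      w4 <- w_sum / 4
      w_ff <- 1 - w_sum
      h <- w_ff * r2
      xs <- torus_steady_fft(w4, h, N, N)
      n_hat <- measure_rf_size(xs, dim = 2)
      if (balanced) {
        wb_sum <- find_critical_balance(w_sum, tau_lag, tau)
        pred <- sqrt(tt * tau_lag / 2)
        horizon <- max(20 * tau, 6 * horizon_factor * pred)
        sim <- simulate_torus(w4, h, N, N, w_bal = wb_sum / 4,
                              tau_lag = tau_lag, dt = dt, T = horizon,
                              tau = tau, x_target = xs)
      } else {
        horizon <- horizon_factor * tt
        sim <- simulate_torus(w4, h, N, N, dt = dt, T = horizon, tau = tau,
                              x_target = xs)
      }
      rt <- measure_response_time(sim$loss)
      if (sim$diverged || !rt$converged) {
        excluded[[length(excluded) + 1]] <- n_hat
      } else {
        rows[[length(rows) + 1]] <- data.frame(size = n_hat, tresp = rt$value,
                                               tresp_target = tt,
                                               w_sum = w_sum)
      }
      if (verbose) message(family, " target=", signif(tt, 3), " n_hat=", n_hat)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2) stop("too few converged runs to fit")
  fit <- fit_power_law(tab$size, tab$tresp)
  structure(list(family = family, table = tab,
                 fit = fit[c("exponent", "prefactor", "r_squared")],
                 excluded = unlist(excluded)),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("Scaling experiment (%s): %d sizes, exponent %.4f, prefactor %.4f\n",
              x$family, nrow(x$table), x$fit$exponent, x$fit$prefactor))
  if (length(x$excluded))
    cat("  excluded (diverged/unconverged):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Per-axis and total synapse counts for P-dimensional grids
#'
#' For a `P`-dimensional stimulus encoded with linear mixed selectivity, the
#' cooperative network needs `3 P` synapses per neuron (`P` feedforward,
#' `2 P` recurrent) while the feedforward implementation needs `P (2 d + 1)`.
#'
#' @param P number of stimulus dimensions.
#' @param d RF width along each axis.
#' @return List with `cooperative` and `feedforward` per-neuron counts.
#' @export
pdim_synapse_counts <- function(P, d) {
  list(cooperative = 3 * P, feedforward = P * (2 * d + 1))
}
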