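#' Receptive-field specification
#'
#' Defines a translation-invariant exponential receptive field (RF) on a ring
#' of `N` neurons: neuron `i` responds to input neuron `j` with weight
#' `gamma^|i-j|`, where `gamma = exp(-1/d)` and `|i-j|` is the periodic
#' distance. The nominal RF size is `n_rf = 2 d + 1`, the number of
#' feedforward synapses a purely feedforward implementation needs per neuron.
#'
#' @param N number of neurons (>= 3).
#' @param d RF width parameter (> 0); may be non-integer, in which case the
#'   nominal size `2 d + 1` is reported without rounding.
#' @return An object of class `rf_spec` with fields `N`, `d`, `gamma`,
#'   `n_rf`, and `boundary = "periodic"`.
#' @examples
#' spec <- rf_spec(200, 2)
#' spec$gamma  # exp(-1/2)
#' @export
rf_spec <- function(N, d) {
  if (!is.numeric(N) || length(N) != 1 || N < 3 || N != round(N))
    stop_param("N must be a single integer >= 3")
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop_param("d must be a single positive number")
  structure(list(N = as.integer(N), d = d, gamma = exp(-1 / d),
                 n_rf = 2 * d + 1, boundary = "periodic"),
            class = "rf_spec")
}

#' @export
print.rf_spec <- function(x, ...) {
  cat(sprintf("RF spec: N = %d, d = %g (gamma = %.6f, nominal size %g), periodic\n",
              x$N, x$d, x$gamma, x$n_rf))
  invisible(x)
}

# Periodic (ring) distance between all index pairs 1..N.
ring_distance <- function(N) {
  idx <- seq_len(N) - 1
  dmat <- abs(outer(idx, idx, "-"))
  pmin(dmat, N - dmat)
}

#' Receptive-field matrix
#'
#' The `N x N` matrix of exponential RFs, `RF[i, j] = gamma^dist(i, j)` with
#' periodic distance. The matrix is symmetric and circulant with unit
#' diagonal, and it equals both the profile of each neuron's RF (rows) and the
#' network response to isolated unit inputs (columns).
#'
#' @param spec an [rf_spec()].
#' @return A dense `N x N` numeric matrix.
#' @export
rf_matrix <- function(spec) {
  if (!inherits(spec, "rf_spec")) stop_param("spec must be an rf_spec")
  spec$gamma^ring_distance(spec$N)
}

#' Cooperative nearest-neighbour weights
#'
#' Weights of the cooperatively coding ring that realizes the exponential RF
#' of width `d` as its stationary state with only three synapses per neuron:
#' `w_rec = gamma / (1 + gamma^2)` to each of the two nearest neighbours and
#' a single feedforward weight `w_ff = 1 - 2 gamma w_rec =
#' (1 - gamma^2) / (1 + gamma^2)`.
#'
#' @param d RF width parameter (> 0).
#' @return A list with `w_rec`, `w_ff` and `gamma`.
#' @examples
#' cooperative_weights(2)
#' @export
cooperative_weights <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop_param("d must be a single positive number")
  g <- exp(-1 / d)
  list(w_rec = g / (1 + g^2), w_ff = (1 - g^2) / (1 + g^2), gamma = g)
}

#' Linear rate-network specification
#'
#' Container for a linear rate network `tau dx/dt = -x + W_rec x + W_ff r`.
#' Matrices may be dense or sparse ([Matrix::Matrix]).
#'
#' @param W_rec recurrent weight matrix (`N x N`).
#' @param W_ff feedforward weight matrix (`N x M`).
#' @param tau membrane time constant (default 1; all times are in units of
#'   `tau` when `tau = 1`).
#' @param topology one of `"ring1d"`, `"ms2d"`, `"torus2d"`, `"generic"`.
#' @param info optional named list of construction parameters.
#' @return An object of class `coopnet_network`.
#' @export
network_spec <- function(W_rec, W_ff, tau = 1,
                         topology = c("generic", "ring1d", "ms2d", "torus2d"),
                         info = list()) {
  topology <- match.arg(topology)
  if (nrow(W_rec) != ncol(W_rec)) stop_param("W_rec must be square")
  if (nrow(W_ff) != nrow(W_rec)) stop_param("W_ff must have as many rows as W_rec")
  if (!is.numeric(tau) || tau <= 0) stop_param("tau must be positive")
  structure(list(N = nrow(W_rec), tau = tau, W_rec = W_rec, W_ff = W_ff,
                 topology = topology, info = info),
            class = "coopnet_network")
}

#' @export
print.coopnet_network <- function(x, ...) {
  cat(sprintf("Linear rate network (%s): N = %d, tau = %g\n",
              x$topology, x$N, x$tau))
  if (length(x$info))
    cat("  ", paste(names(x$info), vapply(x$info, format, ""),
                    sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Cooperatively coding ring network
#'
#' The nearest-neighbour ring whose stationary response to any input equals
#' the exponential RF transform: two recurrent synapses of strength `w_rec`
#' per neuron plus one diagonal feedforward synapse `w_ff`.
#'
#' @inheritParams rf_spec
#' @param tau membrane time constant.
#' @return A `coopnet_network` with `topology = "ring1d"`.
#' @examples
#' net <- cooperative_ring(200, 2)
#' @export
cooperative_ring <- function(N, d, tau = 1) {
  spec <- rf_spec(N, d)
  w <- cooperative_weights(d)
  idx <- seq_len(N)
  up <- idx %% N + 1
  W_rec <- Matrix::sparseMatrix(i = c(idx, up), j = c(up, idx),
                                x = w$w_rec, dims = c(N, N))
  W_ff <- Matrix::Diagonal(N, w$w_ff)
  network_spec(W_rec, W_ff, tau = tau, topology = "ring1d",
               info = list(kind = "cooperative", d = d, gamma = w$gamma,
                           w_rec = w$w_rec, w_ff = w$w_ff,
                           w_sum_rec = 2 * w$w_rec))
}

#' Feedforward ring network
#'
#' The purely feedforward implementation of the same RFs: `W_ff = RF`
#' (optionally truncated to the `2 d + 1` synapses within distance `d`) and
#' no recurrent synapses.
#'
#' @inheritParams cooperative_ring
#' @param truncated if `TRUE`, keep only synapses with periodic distance
#'   `<= d` (the `n_rf = 2 d + 1` relevant synapses per neuron).
#' @return A `coopnet_network`.
#' @export
feedforward_ring <- function(N, d, tau = 1, truncated = FALSE) {
  spec <- rf_spec(N, d)
  W_ff <- rf_matrix(spec)
  if (truncated) W_ff[ring_distance(N) > d] <- 0
  network_spec(Matrix::Matrix(0, N, N, sparse = TRUE), W_ff, tau = tau,
               topology = "ring1d",
               info = list(kind = "feedforward", d = d, truncated = truncated,
                           w_sum_rec = 0))
}

#' Stationary network response
#'
#' Solves the fixed-point equation `x = W_rec x + W_ff r`, i.e.
#' `x = (1 - W_rec)^{-1} W_ff r`. Dense solve for `N <= 1000`, sparse solve
#' above. Errors if the recurrent spectral radius reaches 1 (no stable steady
#' state).
#'
#' @param net a `coopnet_network`.
#' @param r input activity vector.
#' @return Steady-state activity vector of length `N`.
#' @export
steady_state <- function(net, r) {
  if (!inherits(net, "coopnet_network")) stop_param("net must be a coopnet_network")
  if (length(r) != ncol(net$W_ff)) stop_param("input length does not match W_ff")
  rho <- spectral_radius(net$W_rec)
  if (rho >= 1 - 1e-12)
    stop_param("recurrent spectral radius >= 1: dynamics have no stable steady state")
  h <- as.numeric(net$W_ff %*% r)
  n <- net$N
  if (n <= 1000 && !inherits(net$W_rec, "sparseMatrix")) {
    as.numeric(solve(diag(n) - as.matrix(net$W_rec), h))
  } else {
    A <- Matrix::Diagonal(n) - net$W_rec
    as.numeric(Matrix::solve(A, h))
  }
}

#' Truncated Neumann-series response
#'
#' The response after `n` synaptic relays,
#' `x = (1 + W_rec + ... + W_rec^{n-1}) W_ff r`, which equals the discretized
#' network dynamics iterated `n` times from the zero state. For stable
#' networks it converges to [steady_state()] as `n` grows; successive orders
#' add the contribution of longer poly-synaptic pathways.
#'
#' @inheritParams steady_state
#' @param n series order (>= 1).
#' @return Activity vector of length `N`.
#' @export
neumann_response <- function(net, r, n) {
  if (!inherits(net, "coopnet_network")) stop_param("net must be a coopnet_network")
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop_param("n must be a positive integer")
  term <- as.numeric(net$W_ff %*% r)
  acc <- term
  if (n > 1) for (k in seq_len(n - 1)) {
    term <- as.numeric(net$W_rec %*% term)
    acc <- acc + term
  }
  acc
}
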