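#' Per-neuron synapse counts by architecture
#'
#' Exact number of synapses per feature neuron for the rate-model
#' architectures. Cooperative counts are independent of the RF width;
#' feedforward counts grow linearly with it.
#'
#' \describe{
#'   \item{`ff_1d`}{`2 d + 1` feedforward synapses.}
#'   \item{`coop_1d`}{3 (two recurrent, one feedforward).}
#'   \item{`coop_1d_balanced`}{6 (adds one E-to-I and two I-to-E).}
#'   \item{`ff_ms`}{`2 (2 d + 1)`.}
#'   \item{`coop_ms`}{6 (four recurrent, two feedforward).}
#'   \item{`coop_ms_balanced`}{11 (adds one E-to-I and four I-to-E).}
#'   \item{`coop_2d`}{5 (four recurrent, one feedforward).}
#'   \item{`coop_2d_balanced`}{10 (adds one E-to-I and four I-to-E).}
#'   \item{`coop_Pdim`}{`3 P` for `P`-dimensional mixed selectivity.}
#'   \item{`ff_Pdim`}{`P (2 d + 1)`.}
#' }
#'
#' For integer counts with non-integer `d`, the nominal size `2 d + 1` is
#' rounded up to the next odd integer.
#'
#' @param arch architecture tag (see above).
#' @param d RF width (required for feedforward architectures).
#' @param P number of stimulus dimensions (for the `Pdim` tags).
#' @param exact if `TRUE` (default) return the possibly fractional nominal
#'   value `2 d + 1`; if `FALSE` round up to an odd integer synapse count.
#' @return Per-neuron synapse count.
#' @export
per_neuron_count <- function(arch, d = NULL, P = 1, exact = TRUE) {
  n_rf <- if (!is.null(d)) {
    if (exact) 2 * d + 1 else 2 * ceiling(d) + 1
  } else NA_real_
  switch(arch,
         ff_1d = { if (is.null(d)) stop_param("d required for ff_1d"); n_rf },
         coop_1d = 3,
         coop_1d_balanced = 6,
         ff_ms = { if (is.null(d)) stop_param("d required for ff_ms"); 2 * n_rf },
         coop_ms = 6,
         coop_ms_balanced = 11,
         coop_2d = 5,
         coop_2d_balanced = 10,
         coop_Pdim = 3 * P,
         ff_Pdim = { if (is.null(d)) stop_param("d required for ff_Pdim"); P * n_rf },
         stop_param("unknown architecture: ", arch))
}

#' Synapse totals for spiking feedforward vs cooperative architectures
#'
#' Per-neuron synaptic inputs with feature populations of size `N_E`:
#' feedforward coding needs `N_FF = n_rf K_FF + K_EE_in` (inputs from `n_rf`
#' input populations plus within-population recurrence), cooperative coding
#' needs `N_CC = K_FF + K_EE_in + 2 K_EE_cross` (one input population, itself
#' and two neighbours). With fixed connection probability `p_EE`, both
#' recurrent indegrees equal `p_EE N_E`. Totals over `N_F` populations are
#' `N_total = N_F N_E N_per_neuron`. The minimal RF size at which the
#' cooperative network saves synapses follows in closed form:
#' `n_rf > 1 + 2 p_EE N_E / K_FF` (equal indegrees: `n_rf > 3`).
#'
#' @param n_rf RF size(s), vector allowed.
#' @param N_E neurons per feature population.
#' @param N_F number of feature populations.
#' @param K_FF feedforward indegree.
#' @param p_EE recurrent connection probability (indegrees `K = p_EE N_E`).
#' @return An object of class `synapse_totals`: list with `table`
#'   (per `n_rf`: per-neuron and total counts), `min_saving_nrf` (exact
#'   closed-form threshold) and the parameters.
#' @export
spiking_totals <- function(n_rf, N_E = 4000, N_F = 41, K_FF = 100,
                           p_EE = 0.1) {
  if (any(c(n_rf, N_E, N_F, K_FF, p_EE) <= 0)) stop_param("parameters must be positive")
  K <- p_EE * N_E
  n_ff <- n_rf * K_FF + K
  n_cc <- K_FF + 3 * K          # K_EE_in + 2 K_EE_cross, all equal to K
  tab <- data.frame(n_rf = n_rf,
                    N_FF_per_neuron = n_ff, N_CC_per_neuron = n_cc,
                    N_FF_total = N_F * N_E * n_ff,
                    N_CC_total = N_F * N_E * n_cc,
                    saves = n_cc < n_ff)
  structure(list(table = tab,
                 min_saving_nrf = min_saving_nrf(N_E, K_FF, p_EE),
                 params = list(N_E = N_E, N_F = N_F, K_FF = K_FF, p_EE = p_EE)),
            class = "synapse_totals")
}

#' @export
print.synapse_totals <- function(x, ...) {
  cat(sprintf("Synapse totals (N_E = %d, N_F = %d, K_FF = %d, p_EE = %g)\n",
              x$params$N_E, x$params$N_F, x$params$K_FF, x$params$p_EE))
  cat(sprintf("  cooperative saves synapses for n_rf > %g\n", x$min_saving_nrf))
  print(x$table)
  invisible(x)
}

#' Minimal RF size for cooperative synapse savings
#'
#' Exact crossover of the per-neuron counts: the cooperative network uses
#' fewer synapses than the feedforward one when
#' `K_FF + 3 K < n_rf K_FF + K`, i.e. `n_rf > 1 + 2 p_EE N_E / K_FF`.
#' The threshold grows linearly with the feature-population size `N_E`.
#'
#' @inheritParams spiking_totals
#' @return The threshold RF size (savings strictly above this value).
#' @export
min_saving_nrf <- function(N_E, K_FF = 100, p_EE = 0.1) {
  1 + 2 * p_EE * N_E / K_FF
}
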