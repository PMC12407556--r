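test_that("Siegert rate is monotone, vanishes for deeply subthreshold drive, and matches Monte Carlo", {
  p <- lif_params()
  rates <- siegert_rate(seq(2, 20, by = 2), params = p)
  expect_true(all(diff(rates) > 0))
  # saturating guard: noiseless subthreshold neuron never fires
  expect_warning(r0 <- siegert_rate(5, sigma = 0.1, params = p), "overflow")
  expect_equal(r0, 0)
  # Euler-Maruyama oracle: single neuron, no synapses, 100 s
  net1 <- structure(list(
    tuning = list(I_on = 12, I_off = 12, x_max = 1, gamma = 0, w_EE_eff = 0,
                  K_EE = 0, params = p),
    N_F = 1L, N_E = 1L, N_I = 0L, balanced = FALSE, n_exc = 1L, n_tot = 1L,
    params = p, center = 1L, pop_id = 1L, n_pops = 1L, pop_size = 1L,
    syn = list(ptr = c(0L, 0L), post = integer(0), delay = integer(0),
               w = numeric(0)),
    x_target = 0, conn_seed = 1), class = "spiking_network")
  run <- simulate_spiking(net1, T_pre = 0, T_stim = 1e5, seed = 7,
                          stat_window = 1e5, record_per_pop = 0)
  pred <- siegert_rate(12, params = p)
  n_spikes <- run$stat_rates * 100
  se <- pred / sqrt(n_spikes)
  expect_lt(abs(run$stat_rates - pred), 3 * se + 0.05 * pred)
})

test_that("threshold-linear fit recovers exact synthetic parameters and flags degeneracy", {
  drive <- seq(0, 20, 0.5)
  rate <- 4.2 * pmax(0, drive - 7.5)
  fit <- fit_threshold_linear(drive, rate, x_max = 100)
  expect_equal(fit$gain, 4.2, tolerance = 1e-4)
  expect_equal(fit$threshold, 7.5, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-3)
  expect_error(fit_threshold_linear(1:2, c(0, 1)), "at least 3")
  expect_error(fit_threshold_linear(seq(0, 5, 1), rep(0, 6), x_max = 100),
               "operating range")
  # Siegert samples at the default noise level are near threshold-linear
  p <- lif_params()
  sfit <- fit_threshold_linear(params = p, x_max = 150)
  expect_gt(sfit$gain, 0)
  expect_lt(sfit$residual_rms, 0.03 * 150)
})

test_that("stage-1 tuning satisfies the threshold-linear self-consistency", {
  p <- lif_params()
  fit <- fit_threshold_linear(params = p, x_max = 150)
  tun <- tune_excitatory(5, x_max = 150, N_E = 400, p_EE = 0.1,
                         params = p, fit = fit)
  N_F <- 21; center <- 11
  dist <- pmin(abs(seq_len(N_F) - center), N_F - abs(seq_len(N_F) - center))
  x <- 150 * tun$gamma^dist
  J <- tun$w_EE * p$tau_m * tun$K_EE / 1000
  drive <- tun$I_off + J * (x[c(2:N_F, 1)] + x + x[c(N_F, 1:(N_F - 1))])
  drive[center] <- drive[center] + tun$I_on - tun$I_off
  pred <- fit$gain * pmax(0, drive - fit$threshold)
  # fixed point holds on the profile core (wrap-around breaks it only where
  # the target is essentially zero)
  core <- dist <= 5
  expect_lt(max(abs(pred[core] - x[core])), 0.02 * 150)
  # n_rf = 1: no recurrent coupling, a single population responds
  tun1 <- tune_excitatory(1, params = p, fit = fit)
  expect_equal(tun1$w_EE, 0)
  expect_equal(tun1$gamma, 0)
  expect_error(tune_excitatory(4, params = p, fit = fit), "odd integer")
})

test_that("connectivity has fixed indegrees, no autapses, bounded delays, and is seed-reproducible", {
  p <- lif_params()
  tun <- tune_excitatory(3, N_E = 60, p_EE = 0.2, params = p)
  net <- spiking_network(tun, N_F = 5, seed = 99)
  n <- net$n_tot
  pre <- rep(seq_len(n), diff(net$syn$ptr))
  post <- net$syn$post + 1L
  expect_true(all(pre != post))                      # no autapses
  K <- tun$K_EE
  # each postsynaptic neuron receives exactly K synapses from each of the
  # three admissible populations
  pre_pop <- net$pop_id[pre]
  for (j in c(1, 150, 299)) {
    from <- pre_pop[post == j]
    expect_equal(as.integer(table(from)), rep(K, 3L))
  }
  expect_true(all(net$syn$delay >= 1 &
                    net$syn$delay <= 2 / p$dt))      # delays within (0, 2] ms
  net2 <- spiking_network(tun, N_F = 5, seed = 99)
  expect_identical(net$syn, net2$syn)                # deterministic draw
  net3 <- spiking_network(tun, N_F = 5, seed = 100)
  expect_false(identical(net$syn$post, net3$syn$post))
})

test_that("a subthreshold noiseless network is silent", {
  p <- lif_params(sigma = 1e-6)
  tun <- tune_excitatory(1, x_max = 150, N_E = 50, p_EE = 0.2, params = p,
                         fit = list(gain = 5, threshold = 6))
  tun$I_on <- 5; tun$I_off <- 5                      # below threshold
  net <- spiking_network(tun, N_F = 3, seed = 1)
  run <- simulate_spiking(net, T_pre = 10, T_stim = 50, seed = 1,
                          stat_window = 40)
  expect_equal(run$total_spikes, 0)
})

test_that("cooperative spiking: tuned network reproduces the exponential profile across seeds", {
  p <- lif_params()
  tun <- tune_excitatory(3, N_E = 300, p_EE = 0.1, params = p)
  net <- spiking_network(tun, N_F = 15, seed = 5)
  run1 <- simulate_spiking(net, T_pre = 150, T_stim = 700, seed = 3,
                           stat_window = 350)
  run2 <- simulate_spiking(net, T_pre = 150, T_stim = 700, seed = 4,
                           stat_window = 350)
  est1 <- estimate_rates_and_rf(run1)
  est2 <- estimate_rates_and_rf(run2)
  # peak near the target rate; neighbours near gamma * x_max
  expect_lt(abs(max(est1$profile) - 150) / 150, 0.1)
  nb <- est1$profile[net$center + 1]
  expect_lt(abs(nb - 150 * exp(-1)) / (150 * exp(-1)), 0.15)
  # stationary rates agree across noise seeds within sampling error
  expect_lt(max(abs(est1$profile - est2$profile)), 8)
  # spike rasters differ between seeds
  expect_false(identical(run1$spikes$t_ms, run2$spikes$t_ms))
  # response-time estimator recovers a plausible, converged time constant
  expect_true(est1$converged)
  expect_gt(est1$tau_resp_ms, 1)
  expect_lt(est1$tau_resp_ms, 100)
})

test_that("rise-fit recovers the exact time constant on synthetic noiseless traces", {
  bin <- 0.5
  tt <- seq(bin / 2, 400, by = bin)
  rate <- 120 * (1 - exp(-tt / 7.3))
  fake <- structure(list(
    stat_rates = 120, binned_rates = matrix(c(rep(0, 100), rate), nrow = 1),
    bin_ms = bin, T_pre = 50, N_F = 1L, center = 1L,
    loss = numeric(0), dt = 0.01), class = "spiking_run")
  est <- estimate_rates_and_rf(fake, rate_floor_frac = 0.5)
  expect_equal(est$tau_resp_ms, 7.3, tolerance = 0.02)
})

test_that("balanced tuning mirrors rates and cancels the added excitation", {
  p <- lif_params()
  tun <- tune_excitatory(3, N_E = 300, p_EE = 0.1, params = p)
  bt <- tune_balanced(tun, s = 1.4)
  expect_equal(bt$w_EE_bar, 1.4 * tun$w_EE)
  # stationary balance: s w_EE K_EE + w_EI K_EI = w_EE K_EE
  K_EI <- round(0.1 * bt$N_I)
  expect_equal(bt$w_EE_bar * tun$K_EE + bt$w_EI * K_EI,
               tun$w_EE * tun$K_EE, tolerance = 1e-12)
  # inhibitory mirror: threshold-linear gain times w_IE K_IE tau_m equals 1
  expect_equal(tun$gain * bt$w_IE * p$tau_m * round(0.1 * tun$N_E) / 1000, 1,
               tolerance = 1e-12)
  expect_error(tune_balanced(tun, s = 1), "exceed 1")
})
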