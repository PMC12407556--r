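test_that("zero balance reproduces the purely excitatory trajectory", {
  N <- 60; d <- 2
  r <- unit_input(N, 20)
  spec <- balanced_spec(d = d, w_bal = 0, tau_lag = 0.1, N = N)
  sim_b <- delayed_integrate(spec, r, dt = 0.01, T = 5, record_stride = 100)
  cw <- cooperative_weights(d)
  sim_e <- simulate_ring(cw$w_rec, cw$w_ff * r, dt = 0.01, T = 5,
                         record_stride = 100)
  expect_lt(max(abs(sim_b$trajectory$states - sim_e$trajectory$states)), 1e-12)
})

test_that("steady state is invariant under the balance strength", {
  N <- 80; d <- 2
  r <- unit_input(N, 30)
  target <- steady_state(cooperative_ring(N, d), r)
  for (wb in c(0, 1, 3)) {
    spec <- balanced_spec(d = d, w_bal = wb, tau_lag = 0.1, N = N)
    sim <- delayed_integrate(spec, r, dt = 0.01, T = 250)
    expect_false(sim$diverged)
    expect_lt(max(abs(sim$x_final - target)) / max(target), 1e-8)
  }
  # excitatory / inhibitory decomposition is recoverable exactly
  spec <- balanced_spec(d = 2, w_bal = 1.5, tau_lag = 0.1)
  expect_equal(spec$w_rec_E, spec$w_net + 1.5)
  expect_equal(spec$w_rec_I, -1.5)
})

test_that("characteristic roots: no-delay limit, critical maximum, and regimes", {
  wn <- 0.99; tl <- 0.1
  cr0 <- characteristic_roots(wn, 0, tl)
  expect_equal(cr0$lambda, 1 - wn, tolerance = 1e-10)
  expect_equal(cr0$omega, 0)
  wc <- find_critical_balance(wn, tl)
  thr <- find_instability_threshold(wn, tl)
  expect_lt(wc, thr)                              # ordering of regimes
  # decay rate is maximized at the critical balance
  lam <- function(wb) characteristic_roots(wn, wb, tl)$lambda
  expect_gt(lam(wc), lam(0.9 * wc))
  expect_gt(lam(wc), lam(0.5 * (wc + thr)))
  expect_equal(characteristic_roots(wn, 0.8 * wc, tl)$regime, "overdamped")
  under <- characteristic_roots(wn, 0.5 * (wc + thr), tl)
  expect_equal(under$regime, "underdamped")
  expect_gt(under$omega, 0)
  # w_sum_net -> 0 limit: finite critical balance, decay faster than 1/tau
  wc0 <- find_critical_balance(0, tl)
  expect_true(is.finite(wc0) && wc0 > 0)
  expect_gt(characteristic_roots(0, wc0, tl)$lambda, 1)
})

test_that("instability threshold is slightly above scaled balance one and shrinks with the lag", {
  thr <- find_instability_threshold(0.99, 0.1)
  expect_gte(0.1 * thr, 1)
  expect_lt(0.1 * thr, 1.01)
  # threshold decreases as the lag grows
  thrs <- sapply(c(0.05, 0.1, 0.2), function(tl)
    find_instability_threshold(0.99, tl))
  expect_true(all(diff(thrs) < 0))
  # strong-excitation bound: E weights can be ~ tau/tau_lag + 1 times net
  wn <- 0.999
  thr2 <- find_instability_threshold(wn, 0.1)
  expect_lt((thr2 + wn) / wn, 1 / 0.1 + 1 + 0.5)
  expect_gt((thr2 + wn) / wn, 1 / 0.1)
})

test_that("simulated divergence brackets the root-predicted threshold within 2 percent", {
  N <- 200; wn_sum <- 0.99; tl <- 0.1
  thr <- find_instability_threshold(wn_sum, tl)
  r <- unit_input(N, 100)
  run <- function(fac) {
    spec <- balanced_spec(w_net = wn_sum / 2, w_bal = fac * thr / 2,
                          tau_lag = tl, N = N)
    delayed_integrate(spec, r, dt = 0.01, T = 600)$diverged
  }
  expect_false(run(0.98))
  expect_true(run(1.02))
})

test_that("loss regimes: monotone decay below critical, oscillatory dips above", {
  N <- 200; wn_sum <- 0.99; tl <- 0.1
  r <- unit_input(N, 100)
  wc <- find_critical_balance(wn_sum, tl)
  run <- function(wb_sum, T = 80) {
    spec <- balanced_spec(w_net = wn_sum / 2, w_bal = wb_sum / 2,
                          tau_lag = tl, N = N)
    delayed_integrate(spec, r, dt = 0.01, T = T)$loss$values
  }
  # offsets as in the regime diagram: +/- 0.02 in scaled balance units
  l_over <- run(wc - 0.02 / tl)
  l_under <- run(wc + 0.02 / tl)
  # skip the constant-init transient and the numerical noise floor
  after <- function(l) { l <- l[-(1:500)]; l[l > 1e-6 * l[1]] }
  expect_true(all(diff(after(l_over)) < 1e-10))
  expect_true(any(diff(after(l_under)) > 1e-8))
  # at critical the loss decays fastest among the three
  l_crit <- run(wc)
  n <- 6000
  expect_lt(l_crit[n], l_over[n])
})

test_that("eigenmode decay at critical balance matches the geometric-mean closed form", {
  wn_sum <- 0.99; tl <- 0.1
  wc <- find_critical_balance(wn_sum, tl)
  lam <- characteristic_roots(wn_sum, wc, tl)$lambda
  pred <- sqrt(analytic_response_time(wn_sum) * tl / 2)
  expect_lt(abs(1 / lam - pred) / pred, 0.3)
  # measured (constant-init) response time exceeds the eigenmode estimate
  spec <- balanced_spec(w_net = wn_sum / 2, w_bal = wc / 2, tau_lag = tl,
                        N = 200)
  sim <- delayed_integrate(spec, unit_input(200, 100), dt = 0.01, T = 60)
  rt <- measure_response_time(sim$loss)
  expect_gt(rt$value, 1 / lam)
  expect_lt(rt$value, 10 * pred)
})

test_that("closed-form balanced response-time predictions", {
  expect_equal(predicted_balanced_response_time(50, 1, 0.1, "1d"),
               25 * sqrt(0.1), tolerance = 1e-12)
  # MS coefficient is smaller by 1/sqrt(2) at equal RF size
  expect_equal(predicted_balanced_response_time(40, 1, 0.1, "ms") /
                 predicted_balanced_response_time(40, 1, 0.1, "1d"),
               1 / sqrt(2), tolerance = 1e-12)
  expect_equal(predicted_balanced_response_time(50, 1, 1e-12),
               25 * sqrt(1e-12), tolerance = 1e-15)
})

test_that("lag must be commensurate with the step", {
  spec <- balanced_spec(d = 2, w_bal = 1, tau_lag = 0.1)
  expect_error(delayed_integrate(spec, unit_input(200, 100), dt = 0.03, T = 1),
               "multiple of dt")
})

test_that("regime diagram reproduces the damping taxonomy on the scaled balance axis", {
  tab <- balance_regime_table(0.99, 0.1)
  expect_true(all(c("scaled_balance", "lambda", "omega", "regime") %in%
                    names(tab)))
  # no oscillation below critical, oscillation above; divergence past the
  # threshold where lambda turns negative
  wc <- find_critical_balance(0.99, 0.1)
  below <- tab$w_sum_bal < wc
  above <- tab$w_sum_bal > wc & tab$lambda > 0
  expect_true(all(tab$omega[below] < 1e-6))
  expect_true(all(tab$omega[above & tab$w_sum_bal > wc * 1.01] > 0))
  expect_true(any(tab$lambda < 0))          # grid extends past divergence
  # decay rate peaks at the critical balance
  peak <- tab$w_sum_bal[which.max(tab$lambda)]
  expect_lt(abs(peak - wc) / wc, 0.06)      # grid resolution
})
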