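test_that("integration reproduces the closed-form feedforward relaxation", {
  net <- feedforward_ring(50, 2)
  r <- unit_input(50, 25)
  xs <- steady_state(net, r)
  traj <- integrate_rate(net, r, dt = 0.01, T = 5, record_stride = 50)
  for (k in seq_along(traj$times)) {
    expected <- xs * (1 - exp(-traj$times[k]))
    expect_lt(max(abs(traj$states[k, ] - expected)), 1e-4 * max(xs))
  }
  # zero input, zero init stays identically zero
  traj0 <- integrate_rate(net, numeric(50), dt = 0.01, T = 1)
  expect_true(all(traj0$states == 0))
  expect_error(integrate_rate(net, rep(NaN, 50), dt = 0.01, T = 1), "NaN")
})

test_that("compiled ring integrator agrees with the generic integrator", {
  N <- 40
  net <- cooperative_ring(N, 2)
  r <- unit_input(N, 10)
  h <- as.numeric(net$W_ff %*% r)
  for (m in c("midpoint", "euler")) {
    traj <- integrate_rate(net, r, dt = 0.01, T = 3, method = m,
                           record_stride = 300)
    sim <- simulate_ring(net$info$w_rec, h, dt = 0.01, T = 3, method = m,
                         record_stride = 300)
    expect_lt(max(abs(traj$states[2, ] - sim$trajectory$states[2, ])), 1e-12)
  }
})

test_that("midpoint and Euler agree to first order on short horizons", {
  N <- 40
  net <- cooperative_ring(N, 2)
  h <- as.numeric(net$W_ff %*% unit_input(N, 10))
  xs <- ring_final <- function(dt, method)
    simulate_ring(net$info$w_rec, h, dt = dt, T = 2, method = method)$x_final
  dev1 <- max(abs(ring_final(0.02, "euler") - ring_final(0.02, "midpoint")))
  dev2 <- max(abs(ring_final(0.01, "euler") - ring_final(0.01, "midpoint")))
  expect_lt(dev1, 0.02)               # O(dt) discrepancy
  expect_lt(dev2, 0.6 * dev1)         # shrinks roughly linearly with dt
})

test_that("L1 loss curve is the pointwise L1 deviation", {
  net <- feedforward_ring(20, 1)
  r <- unit_input(20, 5)
  xs <- steady_state(net, r)
  traj <- integrate_rate(net, r, dt = 0.01, T = 1)
  lc <- l1_loss_curve(traj, xs)
  expect_equal(lc$values[1], sum(abs(xs)))         # zero state at t = 0
  # trajectory already at target gives identically zero loss
  traj_at <- integrate_rate(net, r, x0 = xs, dt = 0.01, T = 0.5)
  expect_lt(max(l1_loss_curve(traj_at, xs)$values), 1e-10)
  # constructed single-mode exponential trajectory gives exponential loss
  tt <- seq(0, 5, 0.1)
  states <- outer(exp(-tt / 2), xs)
  lc2 <- l1_loss_curve(new_traj <- structure(list(times = tt, states = states,
                                                  dt = 0.1, method = "synthetic",
                                                  diverged = FALSE),
                                             class = "coopnet_trajectory"), 0 * xs)
  expect_equal(lc2$values, sum(abs(xs)) * exp(-tt / 2), tolerance = 1e-12)
})

test_that("response time uses the last up-crossing of the e^-1 threshold", {
  tt <- seq(0, 1000, 0.5)
  rt <- measure_response_time(exp(-tt / 100), times = tt)
  expect_equal(rt$value, 100, tolerance = 0.01)
  expect_equal(rt$value, reference_last_crossing(tt, exp(-tt / 100)))
  # transient re-crossing: measurement moves to the final crossing
  vals <- exp(-tt / 50)
  vals[tt >= 300 & tt <= 320] <- 0.8
  rt2 <- measure_response_time(vals, times = tt)
  expect_equal(rt2$value, 320.5, tolerance = 1e-9)
  expect_equal(rt2$value, reference_last_crossing(tt, vals))
  # never dropping below threshold -> not converged
  rt3 <- measure_response_time(rep(1, 100), times = seq_len(100))
  expect_false(rt3$converged)
  expect_true(is.na(rt3$value))
})

test_that("analytic response time matches theory and flags instability", {
  expect_equal(analytic_response_time(0), 1)
  expect_equal(analytic_response_time(0.99), 100)
  expect_equal(analytic_response_time(0.5, tau = 2), 4)
  expect_error(analytic_response_time(1), "unstable")
  # d = 2: exact circulant value vs quadratic approximation
  ap <- approx_response_time(2)
  expect_equal(ap$exact, 1 / (1 - 2 * 0.443409441985), tolerance = 1e-9)
  expect_equal(ap$quadratic, 9)
  expect_equal(round(ap$exact, 3), 8.835)
})

test_that("circulant spectrum comes from the DFT of the first row", {
  N <- 16; w <- 0.3
  idx <- seq_len(N); up <- idx %% N + 1
  W <- matrix(0, N, N); W[cbind(idx, up)] <- w; W[cbind(up, idx)] <- w
  ev <- sort(Re(circulant_spectrum(W)))
  ev_dense <- sort(Re(eigen(W, only.values = TRUE)$values))
  expect_equal(ev, ev_dense, tolerance = 1e-10)
  expect_equal(max(ev), sum(W[1, ]), tolerance = 1e-12)   # row sum
  expect_equal(circulant_spectrum(matrix(0, 5, 5)), rep(0, 5))
  W[2, 3] <- 0.9
  expect_error(circulant_spectrum(W), "not circulant")
})

test_that("RF-size inversion returns the summed cooperative weight", {
  for (n_rf in c(6, 14, 50)) {
    d <- (n_rf - 1) / 2
    expect_equal(wsum_for_rf_size(n_rf), 2 * cooperative_weights(d)$w_rec)
  }
  expect_error(wsum_for_rf_size(1), "exceed 1")
})

test_that("divergence is flagged, not raised, for unstable rings", {
  sim <- simulate_ring(0.6, unit_input(50, 10) * 0.01, dt = 0.01, T = 300,
                       x_target = numeric(50))
  expect_true(sim$diverged)
  expect_true(any(!is.finite(sim$loss$values)) ||
                max(sim$loss$values, na.rm = TRUE) > 1e3)
})
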