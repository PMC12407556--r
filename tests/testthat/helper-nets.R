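# Shared fixtures: all built in code, deterministic.

unit_input <- function(N, j0) { r <- numeric(N); r[j0] <- 1; r }

# dense brute-force reference for the discretized dynamics
# x((n+1)tau) = W_rec x(n tau) + W_ff r, from zero state
brute_force_discrete <- function(W_rec, W_ff, r, n) {
  x <- numeric(nrow(W_rec))
  h <- as.numeric(W_ff %*% r)
  for (k in seq_len(n)) x <- as.numeric(W_rec %*% x) + h
  x
}

# reference response-time measurement: direct scan for the last up-crossing
reference_last_crossing <- function(times, vals, frac = exp(-1)) {
  thr <- vals[1] * frac
  t_ok <- NA_real_
  for (i in seq_along(vals)) {
    if (all(vals[i:length(vals)] < thr)) { t_ok <- times[i]; break }
  }
  t_ok
}
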