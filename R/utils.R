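`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

#' @useDynLib coopnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft lm coef optimize pnorm rnorm runif uniroot nls predict
#' @importFrom utils write.csv head tail
NULL

# Circulant steady state of the nearest-neighbour ring via the DFT:
# x = (1 - W_rec)^{-1} h with eigenvalues 2 w cos(2 pi k / N).
ring_steady_fft <- function(w_side, h) {
  n <- length(h)
  lam <- 2 * w_side * cos(2 * pi * (seq_len(n) - 1) / n)
  if (max(lam) >= 1) stop_param("recurrent spectrum reaches 1; no stable steady state")
  Re(fft(fft(h) / (1 - lam), inverse = TRUE)) / n
}

# Same for the four-neighbour torus (nx-by-ny grid, column-major h).
torus_steady_fft <- function(w, h, nx, ny) {
  hm <- matrix(h, nx, ny)
  lam <- 2 * w * (outer(cos(2 * pi * (seq_len(nx) - 1) / nx),
                        rep(1, ny)) +
                  outer(rep(1, nx),
                        cos(2 * pi * (seq_len(ny) - 1) / ny)))
  if (max(lam) >= 1) stop_param("recurrent spectrum reaches 1; no stable steady state")
  as.vector(Re(fft(fft(hm) / (1 - lam), inverse = TRUE)) / (nx * ny))
}

# Spectral radius by power iteration (adequate for the non-negative
# connectivity matrices used here; falls back to dense eigen for small N).
spectral_radius <- function(W, iter = 200, tol = 1e-10) {
  n <- nrow(W)
  if (n <= 400 && !inherits(W, "sparseMatrix")) {
    return(max(Mod(eigen(as.matrix(W), only.values = TRUE)$values)))
  }
  v <- rep(1 / sqrt(n), n)
  est <- 0
  for (k in seq_len(iter)) {
    v2 <- as.numeric(W %*% v)
    nrm <- sqrt(sum(v2^2))
    if (nrm == 0) return(0)
    v2 <- v2 / nrm
    if (abs(nrm - est) < tol * max(1, est)) { est <- nrm; break }
    est <- nrm
    v <- v2
  }
  est
}
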