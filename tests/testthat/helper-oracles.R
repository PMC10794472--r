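# Independent oracles and fixture builders. These deliberately avoid the
# package's own numerical code paths (pa_expm / pa_pinv / projections).

# Truncated-series matrix exponential with plain repeated squaring.
expm_series <- function(M, terms = 30L) {
  n <- nrow(M)
  s <- 0L
  nrm <- max(abs(M)) * n
  while (nrm > 0.25) {
    s <- s + 1L
    nrm <- nrm / 2
  }
  A <- M / 2^s
  E <- diag(1, n)
  P <- diag(1, n)
  fact <- 1
  for (k in seq_len(terms)) {
    P <- P %*% A
    fact <- fact * k
    E <- E + P / fact
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# QR-based least-squares reconstruction of Yf from the rows of Yp:
# each row of Yf is regressed on the rows of Yp (normal-equations oracle,
# solved by QR for numerical independence from the SVD path).
proj_oracle <- function(Yf, Yp) {
  coefs <- qr.coef(qr(t(Yp)), t(Yf))
  coefs[is.na(coefs)] <- 0
  t(t(Yp) %*% coefs)
}

# Quick labeled modal trace at the default analysis rate.
make_modal_signal <- function(alpha = 4e-7, omega_n = 2.85e7, c1 = 1, c2 = 0.8,
                              ts = 1e-8, n = 120, label = "unlabeled") {
  y <- modal_impulse_response(pa_modal_params(alpha, omega_n, c1, c2), ts, n)
  pa_signal(y, ts = ts, label = label)
}

# Random underdamped modal parameter draw in the plausible PA band.
random_modal_params <- function() {
  pa_modal_params(alpha = runif(1, 2e-7, 6e-7),
                  omega_n = runif(1, 2.5e7, 3.5e7),
                  c1 = runif(1, 0.3, 1.2),
                  c2 = runif(1, 0.1, 0.9))
}

# 2-D correlated Gaussian draws via Cholesky (for ellipse coverage).
rmvnorm2 <- function(n, mean = c(0, 0), S = diag(2)) {
  L <- chol(S)
  sweep(matrix(rnorm(2 * n), n, 2) %*% L, 2, mean, "+")
}
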