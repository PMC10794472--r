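test_that("build_hankel indexing, shapes and errors", {
  h <- build_hankel(0:5, i = 1)
  expect_equal(h$Yp, matrix(0:4, 1))
  expect_equal(h$Yf, matrix(1:5, 1))
  expect_equal(h$j, 5L)
  # shape contract across sizes
  for (i in c(2L, 5L, 8L)) {
    y <- rnorm(40)
    h <- build_hankel(y, i)
    expect_equal(dim(h$Yp), c(i, 40L - 2L * i + 1L))
    expect_equal(dim(h$Yf), c(i, 40L - 2L * i + 1L))
    # entry (r, c) of [Yp; Yf] is y(r + c), 0-based
    H <- rbind(h$Yp, h$Yf)
    for (r in c(1L, i, 2L * i)) {
      expect_equal(H[r, ], y[r:(r + h$j - 1L)])
    }
  }
  hc <- build_hankel(rep(3.5, 12), i = 3)
  expect_true(all(hc$Yp == 3.5) && all(hc$Yf == 3.5))
  expect_error(build_hankel(1:8, i = 4), "at least 9 samples")
})

test_that("projection equals the least-squares oracle and is idempotent", {
  set.seed(21)
  # rows of Yf already in rowspace(Yp) -> projection is the identity map
  Yp <- matrix(rnorm(24), 3, 8)
  R <- matrix(rnorm(9), 3, 3)
  h <- structure(list(Yp = Yp, Yf = R %*% Yp, i = 3L, j = 8L), class = "pa_hankel")
  expect_equal(project_future_onto_past(h), R %*% Yp, tolerance = 1e-10)
  # rows orthogonal to rowspace(Yp) -> zero
  q <- qr.Q(qr(t(rbind(Yp, rnorm(8), rnorm(8)))))
  Yf_orth <- t(q[, 4:5]) %*% (diag(8) - q[, 1:3] %*% t(q[, 1:3]))
  Yf_orth <- matrix(rnorm(2 * 8), 2, 8)
  Yf_orth <- Yf_orth - Yf_orth %*% t(Yp) %*% solve(Yp %*% t(Yp)) %*% Yp
  h2 <- structure(list(Yp = Yp, Yf = Yf_orth, i = 2L, j = 8L), class = "pa_hankel")
  expect_lt(max(abs(project_future_onto_past(h2))), 1e-10)
  # random cases against the QR normal-equations oracle (incl. rank-deficient)
  for (rep in 1:20) {
    Yp <- matrix(rnorm(24), 3, 8)
    if (rep %% 4 == 0) Yp[3, ] <- Yp[1, ] + Yp[2, ]  # rank-deficient past
    Yf <- matrix(rnorm(24), 3, 8)
    h3 <- structure(list(Yp = Yp, Yf = Yf, i = 3L, j = 8L), class = "pa_hankel")
    expect_equal(project_future_onto_past(h3), proj_oracle(Yf, Yp),
                 tolerance = 1e-8)
  }
})

test_that("weighted_svd: diagonal case, reconstruction, rank detection", {
  s <- weighted_svd(diag(c(3, 1)))
  expect_equal(s$d, c(3, 1))
  set.seed(22)
  Oi <- matrix(rnorm(40), 5, 8)
  W1 <- diag(5) + 0.1 * matrix(rnorm(25), 5, 5)
  W2 <- diag(8)
  s2 <- weighted_svd(Oi, W1, W2)
  expect_lt(max(abs(s2$u %*% diag(s2$d) %*% t(s2$v) - W1 %*% Oi %*% W2)), 1e-10)
  expect_true(all(diff(s2$d) <= 0))
  expect_lt(max(abs(crossprod(s2$u) - diag(ncol(s2$u)))), 1e-10)
  # rank-2 outer-product construction -> exactly 2 singular values above tol
  a <- rnorm(6); b <- rnorm(9); cc <- rnorm(6); d <- rnorm(9)
  s3 <- weighted_svd(outer(a, b) + outer(cc, d))
  expect_equal(sum(s3$d > 1e-10 * s3$d[1]), 2L)
  expect_error(weighted_svd(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("estimate_order: gap rule, override, degenerate input", {
  expect_equal(as.integer(estimate_order(c(10, 5, 1e-4, 1e-5))), 2L)
  expect_equal(as.integer(estimate_order(c(10, 5, 1e-4, 1e-5), override = 3)), 3L)
  expect_error(estimate_order(rep(0, 4)), "indistinguishable from zero")
  # noise-free second-order signal -> 2; fourth-order (two modal pairs) -> 4
  y2 <- modal_impulse_response(pa_modal_params(4e-7, 2.85e7, 1, 0.8), 1e-8, 120)
  fit2 <- identify_ss(pa_signal(y2, 1e-8))
  expect_equal(fit2$model$order, 2L)
  y4 <- y2 + modal_impulse_response(pa_modal_params(3e-7, 1.4e7, 0.7, 0.2), 1e-8, 120)
  fit4 <- identify_ss(pa_signal(y4, 1e-8))
  expect_equal(fit4$model$order, 4L)
  # noise-free SV log-gap at k = 2 spans >= 4 decades
  expect_gte(fit2$log_gaps[2], 4)
})

test_that("observability and state estimates factor the projection", {
  y <- modal_impulse_response(pa_modal_params(4e-7, 3e7, 1, 0.5), 1e-8, 120)
  h <- build_hankel(y, 20L)
  Oi <- project_future_onto_past(h)
  sv <- weighted_svd(Oi)
  dec <- observability_and_states(sv, Oi, h, 2L)
  # Gamma_i = U Sigma^{1/2} under identity weighting
  expect_equal(dec$Gamma_i, sv$u[, 1:2] %*% diag(sqrt(sv$d[1:2])))
  # Oi = Gamma_i Xi for an (exactly) rank-2 projection
  expect_lt(max(abs(dec$Gamma_i %*% dec$Xi - Oi)), 1e-8 * max(abs(Oi)))
  expect_equal(dim(dec$Xi), c(2L, h$j))
  expect_equal(dim(dec$Xi_plus), c(2L, h$j))
  expect_error(observability_and_states(sv, Oi, h, 15L), "rank")
})

test_that("solve_system_matrices recovers a known generating model", {
  # known stable (A0, B0, C0); data = its impulse response, noise-free
  set.seed(23)
  for (rep in 1:5) {
    p <- random_modal_params()
    ts <- 1e-8
    lam <- exp((-1 / p$alpha + 1i * p$omega_n) * ts)
    A0 <- matrix(c(Re(lam), -Im(lam), Im(lam), Re(lam)), 2, 2)
    B0 <- c(1, 0.3)
    C0 <- c(0.8, -0.4)
    m0 <- pa_ss_model(A0, B0, C0, ts = ts)
    y <- impulse_response(m0, 120)
    fit <- identify_ss(pa_signal(y, ts))
    expect_gte(fit$nrmse, 99.9)
    ev0 <- sort(eigen(A0, only.values = TRUE)$values)
    ev <- sort(eigen(fit$model$A, only.values = TRUE)$values)
    expect_lt(max(Mod(ev - ev0) / Mod(ev0)), 1e-6)
    expect_equal(dim(fit$model$B), c(2L, 1L))
    expect_equal(dim(fit$model$C), c(1L, 2L))
    # shifted states obey the fitted dynamics (impulse input is zero inside
    # the Hankel columns, so Xi_plus ~ A Xi)
    dec <- fit$decomposition
    expect_lt(max(abs(dec$Xi_plus - fit$model$A %*% dec$Xi)),
              1e-6 * max(abs(dec$Xi)))
  }
  # degenerate all-zero signal
  expect_error(identify_ss(pa_signal(rep(0, 100), 1e-8)), "all-zero")
})

test_that("identify_ss is deterministic, stable, and accurate under noise", {
  cfg <- pa_sim_config(snr_db = 40)
  p <- pa_modal_params(4e-7, 2.85e7, 1, 0.8)
  set.seed(31); s1 <- simulate_signal(p, 6.56e-6, cfg)
  f1 <- identify_ss(s1)
  f2 <- identify_ss(s1)
  expect_identical(f1$model$A, f2$model$A)
  expect_identical(f1$model$B, f2$model$B)
  # SNR 40 dB reconstruction quality, 50 seeds, report the minimum
  set.seed(32)
  fits <- vapply(1:50, function(r) {
    s <- simulate_signal(p, 6.56e-6, cfg)
    fit <- identify_ss(s, order_override = 2L)
    # stability of the fitted dynamics for decaying inputs
    expect_true(all(Mod(eigen(fit$model$A, only.values = TRUE)$values) < 1))
    fit$nrmse
  }, numeric(1))
  expect_gte(min(fits), 97)
})

test_that("identification at the hardware rate decimates and still fits", {
  cfg_fast <- pa_sim_config(ts = 2e-9, snr_db = "none")  # 500 MS/s input
  p <- pa_modal_params(4e-7, 2.85e7, 1, 0.8)
  s <- simulate_signal(p, 6.56e-6, cfg_fast)
  fit <- identify_ss(s, decimate_to = 1e8)
  expect_equal(fit$ts_used, 1e-8)
  expect_equal(fit$model$order, 2L)
  expect_gte(fit$nrmse, 99.5)
})

test_that("impulse_response conventions", {
  m <- pa_ss_model(matrix(0), 1, 3, ts = 1)
  expect_equal(impulse_response(m, 3), c(3, 0, 0))
  m2 <- pa_ss_model(matrix(0.5), 1, 1, ts = 1)
  expect_equal(impulse_response(m2, 4), c(1, 0.5, 0.25, 0.125))
  # modal-form discrete sampling matches the closed-form damped sinusoid
  p <- pa_modal_params(5e-7, 3e7, 1.2, -0.4)
  ts <- 1e-8
  Abar_c <- matrix(c(-1 / p$alpha, -p$omega_n, p$omega_n, -1 / p$alpha), 2, 2)
  Ad <- expm_series(Abar_c * ts)
  md <- pa_ss_model(Ad, c(1, 0), c(p$c1, -p$c2), ts = ts)
  expect_equal(impulse_response(md, 100),
               modal_impulse_response(p, ts, 100), tolerance = 1e-10)
})

test_that("nrmse analytic values and guards", {
  y <- c(1, 2, 3)
  expect_equal(nrmse(y, y), 100)
  expect_equal(nrmse(y, rep(mean(y), 3)), 0)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 4)), (1 - 1 / sqrt(2)) * 100)
  expect_lte(nrmse(y, c(0, 5, 1)), 100)
  expect_error(nrmse(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(nrmse(1:3, 1:4), "length")
})

test_that("noise-free parameter recovery: discrete eigenvalues to 1e-4", {
  set.seed(33)
  worst <- 0
  for (rep in 1:100) {
    p <- random_modal_params()
    ts <- 1e-8
    y <- modal_impulse_response(p, ts, 120)
    fit <- identify_ss(pa_signal(y, ts))
    lam_true <- exp((-1 / p$alpha + 1i * p$omega_n) * ts)
    lam_hat <- eigen(fit$model$A, only.values = TRUE)$values
    err <- min(Mod(lam_hat - lam_true)) / Mod(lam_true)
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-4)
})
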