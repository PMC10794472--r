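# Subspace identification of a single-output state-space model from one PA
# trace: block-Hankel past/future split, orthogonal projection of the future
# outputs onto the past row space, SVD with gap-based order selection,
# extended observability matrix and state-sequence estimates, and a final
# shift-invariance least-squares solve for (A, B, C).

#' Discrete/continuous state-space model container
#'
#' @param A `n x n` system matrix.
#' @param B `n x 1` input matrix.
#' @param C `1 x n` output matrix.
#' @param ts sampling interval in seconds (bookkeeping for both domains).
#' @param domain `"discrete"` or `"continuous"`.
#' @return an object of class `pa_ss_model`.
#' @export
pa_ss_model <- function(A, B, C, ts, domain = c("discrete", "continuous")) {
  domain <- match.arg(domain)
  A <- as.matrix(A)
  B <- matrix(as.numeric(B), ncol = 1)
  C <- matrix(as.numeric(C), nrow = 1)
  n <- nrow(A)
  if (ncol(A) != n || nrow(B) != n || ncol(C) != n) {
    stop("pa_ss_model: inconsistent matrix dimensions")
  }
  if (!all(is.finite(A), is.finite(B), is.finite(C))) {
    stop("pa_ss_model: non-finite entries")
  }
  structure(list(A = A, B = B, C = C, ts = ts, order = n, domain = domain),
            class = "pa_ss_model")
}

#' @export
print.pa_ss_model <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  cat(sprintf("<pa_ss_model> order %d, %s time, ts = %.4g s\n",
              x$order, x$domain, x$ts))
  cat("  eigenvalues:", paste(format(ev, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Build the past/future block-Hankel split
#'
#' Stacks shifted windows of `y` into a `2i x j` block-Hankel matrix whose
#' entry `(r, c)` (0-based) is `y(r + c)`, then splits it into `Yp` (first `i`
#' rows, "past") and `Yf` (last `i` rows, "future"), with `j = N - 2i + 1`.
#'
#' @param y numeric trace of length `N >= 2i + 1`.
#' @param i block-row half count (>= 1; >= 2 for the full identification).
#' @return an object of class `pa_hankel` with elements `Yp`, `Yf`, `i`, `j`.
#' @examples
#' h <- build_hankel(0:5, i = 1)
#' h$Yp  # 0 1 2 3 4
#' @export
build_hankel <- function(y, i) {
  y <- as.numeric(y)
  N <- length(y)
  i <- as.integer(i)
  if (i < 1L) stop("build_hankel: i must be >= 1")
  if (N < 2L * i + 1L) {
    stop(sprintf("build_hankel: trace too short (N = %d); need at least %d samples for i = %d",
                 N, 2L * i + 1L, i))
  }
  j <- N - 2L * i + 1L
  H <- matrix(0, 2L * i, j)
  for (r in seq_len(2L * i)) H[r, ] <- y[r:(r + j - 1L)]
  structure(list(Yp = H[seq_len(i), , drop = FALSE],
                 Yf = H[(i + 1L):(2L * i), , drop = FALSE],
                 i = i, j = j),
            class = "pa_hankel")
}

#' Project future outputs onto the past row space
#'
#' Computes `Oi = Yf Yp' (Yp Yp')^+ Yp`, the orthogonal projection of the rows
#' of `Yf` onto the row space of `Yp` -- the output-only reduction of the
#' oblique projection used when the only excitation is a canonical impulse.
#' Rank deficiency is handled by the pseudo-inverse.
#'
#' @param h a [build_hankel()] result.
#' @return matrix `Oi` with the shape of `Yf`.
#' @export
project_future_onto_past <- function(h) {
  stopifnot(inherits(h, "pa_hankel"))
  project_rows_onto(h$Yf, h$Yp)
}

#' Weighted singular value decomposition of the projection
#'
#' SVD of `W1 %*% Oi %*% W2` with singular values in non-increasing order.
#' The package default (used by [identify_ss()]) is identity weighting.
#'
#' @param Oi projection matrix.
#' @param W1,W2 weighting matrices (`NULL` for identity).
#' @return list with `u`, `d`, `v` (as [base::svd()]) plus `W1`, `W2`.
#' @export
weighted_svd <- function(Oi, W1 = NULL, W2 = NULL) {
  M <- as.matrix(Oi)
  if (!all(is.finite(M))) stop("weighted_svd: non-finite entries")
  if (!is.null(W1)) M <- W1 %*% M
  if (!is.null(W2)) M <- M %*% W2
  s <- svd(M)
  s$W1 <- W1
  s$W2 <- W2
  s
}

#' Estimate the model order from the singular-value gap
#'
#' Returns the index `k` (within `1..max_order`) maximizing the log-gap
#' `log10(sigma_k / sigma_(k+1))`; singular values below the absolute floor
#' `1e-12 * sigma_1` are clamped to the floor so the criterion is defined for
#' numerically zero tails. An explicit `override` short-circuits the rule.
#'
#' @param sigma singular values, non-increasing, at least 2 of them.
#' @param max_order largest order considered (default 10).
#' @param override optional fixed order.
#' @return estimated order (integer), with the log-gap profile attached as
#'   attribute `"log_gaps"`.
#' @export
estimate_order <- function(sigma, max_order = 10L, override = NULL) {
  sigma <- as.numeric(sigma)
  if (length(sigma) < 2L) stop("estimate_order: need at least 2 singular values")
  if (!is.null(override)) return(as.integer(override))
  floor_eps <- 1e-12 * sigma[1]
  if (sigma[1] <= 0 || all(sigma <= floor_eps)) {
    stop("estimate_order: signal indistinguishable from zero")
  }
  s <- pmax(sigma, floor_eps)
  K <- min(as.integer(max_order), length(s) - 1L)
  gaps <- log10(s[seq_len(K)] / s[seq_len(K) + 1L])
  n_hat <- which.max(gaps)
  structure(as.integer(n_hat), log_gaps = gaps)
}

#' Observability matrix and state-sequence estimates
#'
#' From the first `n_hat` singular triplets builds the extended observability
#' matrix `Gamma_i = W1^{-1} U Sigma^{1/2}` (identity `W1` here), the state
#' sequence `Xi = Gamma_i^+ Oi`, and the one-step-shifted sequence
#' `Xi_plus = Gamma_{i-1}^+ O_{i-1}`, where `Gamma_{i-1}` drops the last block
#' row of `Gamma_i` and `O_{i-1}` projects the shifted future block `Yf^-`
#' onto the extended past `Yp^+` (first row of `Yf` moved to the past). Both
#' state sequences have `j` columns and are column-aligned (columns are states
#' at times `i..i+j-1` and `i+1..i+j`).
#'
#' @param sv a [weighted_svd()] result.
#' @param Oi the projection the SVD was taken of.
#' @param h the [build_hankel()] split.
#' @param n_hat selected order.
#' @return an object of class `pa_subspace_decomp` with `Gamma_i`, `Xi`,
#'   `Xi_plus`, `Yii` (the single-row output block), `sigma`, `order_estimate`.
#' @export
observability_and_states <- function(sv, Oi, h, n_hat) {
  stopifnot(inherits(h, "pa_hankel"))
  if (h$i < 2L) stop("observability_and_states: need i >= 2")
  n_hat <- as.integer(n_hat)
  if (n_hat < 1L) stop("observability_and_states: order must be >= 1")
  if (n_hat > length(sv$d) || sv$d[n_hat] <= 1e-12 * sv$d[1]) {
    stop("observability_and_states: requested order exceeds the available rank")
  }
  U1 <- sv$u[, seq_len(n_hat), drop = FALSE]
  Gamma <- U1 %*% diag(sqrt(sv$d[seq_len(n_hat)]), n_hat)
  if (!is.null(sv$W1)) Gamma <- solve(sv$W1) %*% Gamma
  Xi <- pa_pinv(Gamma) %*% Oi
  Yf_minus <- h$Yf[-1L, , drop = FALSE]
  Yp_plus <- rbind(h$Yp, h$Yf[1L, , drop = FALSE])
  Oi_minus <- project_rows_onto(Yf_minus, Yp_plus)
  Gamma_m1 <- Gamma[-nrow(Gamma), , drop = FALSE]
  Xi_plus <- pa_pinv(Gamma_m1) %*% Oi_minus
  structure(
    list(Oi = Oi, U = sv$u, sigma = sv$d, V = sv$v,
         Gamma_i = Gamma, Xi = Xi, Xi_plus = Xi_plus,
         Yii = h$Yf[1L, , drop = FALSE], order_estimate = n_hat),
    class = "pa_subspace_decomp"
  )
}

#' Solve for the system matrices
#'
#' Solves the stacked least-squares problem
#' `[Xi_plus; Yii] = [[A; C]] Xi` for `A` and `C` (the excitation is a unit
#' impulse at the aligned onset sample, so the input block `U_i` inside the
#' Hankel columns is identically zero and drops out), then recovers `B` as the
#' least-squares initial-state fit of the model impulse response
#' `y(k) = C A^k B` to the measured trace.
#'
#' @param dec a [observability_and_states()] decomposition.
#' @param y the (onset-aligned, decimated) trace used to build the Hankel split.
#' @param ts sampling interval of `y` in seconds.
#' @return a discrete-time [pa_ss_model()].
#' @export
solve_system_matrices <- function(dec, y, ts) {
  stopifnot(inherits(dec, "pa_subspace_decomp"))
  n <- dec$order_estimate
  Xi <- dec$Xi
  sx <- svd(Xi)$d
  if (length(sx) < n || sx[n] <= max(dim(Xi)) * .Machine$double.eps * sx[1] * 10) {
    stop("solve_system_matrices: rank-deficient state regressor; ",
         "try a larger Hankel half-size i or coarser decimation")
  }
  Theta <- rbind(dec$Xi_plus, dec$Yii)
  M <- Theta %*% pa_pinv(Xi)
  A <- M[seq_len(n), , drop = FALSE]
  C <- M[n + 1L, , drop = FALSE]
  # B as initial-state least squares against the full aligned trace:
  # rows of G are C, CA, CA^2, ... (extended observability over the window).
  N <- length(y)
  G <- matrix(0, N, n)
  g <- C
  for (k in seq_len(N)) {
    G[k, ] <- g
    g <- g %*% A
  }
  B <- pa_pinv(G) %*% y
  pa_ss_model(A, B, C, ts = ts, domain = "discrete")
}

# Anti-alias FIR low-pass (windowed sinc, Hamming) + downsample by M.
decimate_trace <- function(y, M) {
  M <- as.integer(M)
  if (M <= 1L) return(y)
  ntaps <- min(8L * M + 1L, 1001L)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  half <- (ntaps - 1L) / 2L
  k <- seq(-half, half)
  fc <- 0.4 / M  # cycles per input sample; 80% of post-decimation Nyquist
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  h <- h * (0.54 + 0.46 * cos(pi * k / half))
  h <- h / sum(h)
  full <- stats::convolve(y, rev(h), type = "open")
  yf <- full[(half + 1L):(half + length(y))]
  yf[seq(1L, length(y), by = M)]
}

#' Identify a state-space model from a PA trace
#'
#' Full subspace pipeline: optional decimation to `decimate_to` samples/s
#' (anti-alias low-pass then downsample), onset alignment (the window is
#' shifted so the first sample with `|y| >= 10%% of max |y|` becomes sample 0),
#' Hankel split, projection, SVD (identity weighting), singular-value-gap
#' order selection, observability/state estimation, and the system-matrix
#' solve. The fitted model's reconstruction NRMSE and the singular values are
#' kept as diagnostics.
#'
#' @param signal a [pa_signal()].
#' @param i Hankel half-size (default 20, well above the expected order 2).
#' @param max_order largest order considered by the gap rule (default 10).
#' @param order_override optional fixed order.
#' @param decimate_to target sampling rate in samples/s (default 1e8);
#'   `NULL` disables decimation.
#' @return an object of class `pa_ident`: list with `model` (discrete
#'   [pa_ss_model()]), `decomposition` ([observability_and_states()] output),
#'   `y_used` (the aligned, decimated trace), `ts_used`, `nrmse` (percent),
#'   `onset_sample` (index into the decimated trace).
#' @export
identify_ss <- function(signal, i = 20L, max_order = 10L,
                        order_override = NULL, decimate_to = 1e8) {
  stopifnot(inherits(signal, "pa_signal"))
  y <- signal$samples
  ts <- signal$ts
  n_skip <- 0L
  if (!is.null(decimate_to)) {
    fs <- 1 / ts
    if (fs > 1.5 * decimate_to) {
      M <- floor(fs / decimate_to + 0.5)
      y <- decimate_trace(y, M)
      ts <- ts * M
      # skip the anti-alias filter's half-length past the onset: those
      # samples ride the filter's rising edge, not the modal response
      ntaps <- min(8L * M + 1L, 1001L)
      if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
      n_skip <- as.integer(ceiling((ntaps - 1L) / 2L / M)) + 1L
    }
  }
  k0 <- onset_index(y)
  k0 <- min(k0 + n_skip, length(y))
  y <- y[k0:length(y)]
  N <- length(y)
  if (N < 2L * i + 1L) {
    stop(sprintf("identify_ss [hankel]: aligned trace too short (N = %d) for i = %d", N, i))
  }
  h <- build_hankel(y, i)
  Oi <- project_future_onto_past(h)
  sv <- weighted_svd(Oi)
  n_hat <- estimate_order(sv$d, max_order = max_order, override = order_override)
  dec <- observability_and_states(sv, Oi, h, n_hat)
  model <- solve_system_matrices(dec, y, ts)
  ev <- eigen(model$A, only.values = TRUE)$values
  if (any(Mod(ev) >= 1)) {
    warning("identify_ss: fitted A has eigenvalue(s) on or outside the unit circle")
  }
  fit <- nrmse(y, impulse_response(model, N))
  structure(
    list(model = model, decomposition = dec, y_used = y, ts_used = ts,
         nrmse = fit, onset_sample = k0,
         log_gaps = attr(n_hat, "log_gaps")),
    class = "pa_ident"
  )
}

#' @export
print.pa_ident <- function(x, ...) {
  cat(sprintf("<pa_ident> order %d model, NRMSE = %.2f%%, %d samples at ts = %.3g s\n",
              x$model$order, x$nrmse, length(x$y_used), x$ts_used))
  invisible(x)
}

#' Impulse response of a discrete model
#'
#' `y(k) = C A^k B` for `k = 0 .. n_points - 1` (the discrete unit impulse is
#' read as the state jump `x(0) = B`), computed by state recursion.
#'
#' @param model a discrete-time [pa_ss_model()].
#' @param n_points number of samples.
#' @return numeric vector of length `n_points`.
#' @export
impulse_response <- function(model, n_points) {
  stopifnot(inherits(model, "pa_ss_model"))
  if (model$domain != "discrete") {
    stop("impulse_response: discrete-time models only; see to_continuous() for ZOH sampling")
  }
  y <- numeric(n_points)
  x <- model$B
  for (k in seq_len(n_points)) {
    y[k] <- drop(model$C %*% x)
    x <- model$A %*% x
  }
  y
}

#' Normalized root-mean-square-error fit score
#'
#' `NRMSE = (1 - ||y - yhat|| / ||y - mean(y)||) * 100` percent:
#' 100 for an exact match, 0 for a fit no better than the signal mean,
#' negative for worse.
#'
#' @param y_meas measured trace (not constant, length >= 2).
#' @param y_model model trace of equal length.
#' @return fit score in percent (<= 100).
#' @export
nrmse <- function(y_meas, y_model) {
  y_meas <- as.numeric(y_meas)
  y_model <- as.numeric(y_model)
  if (length(y_meas) != length(y_model)) stop("nrmse: length mismatch")
  if (length(y_meas) < 2L) stop("nrmse: need at least 2 samples")
  denom <- sqrt(sum((y_meas - mean(y_meas))^2))
  if (denom == 0) stop("nrmse: constant measured signal (zero denominator)")
  (1 - sqrt(sum((y_meas - y_model)^2)) / denom) * 100
}
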