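# Small dense linear-algebra helpers shared across the identification and
# modal-conversion code. These are deliberately plain SVD/eigen based
# routines: every matrix here is tiny (at most ~40 x ~100).

#' Moore-Penrose pseudo-inverse
#'
#' SVD-based pseudo-inverse with the standard cutoff
#' `max(dim(M)) * eps * sigma_1` unless an explicit tolerance is supplied.
#'
#' @param M numeric matrix.
#' @param tol absolute singular-value cutoff; `NULL` for the default.
#' @return the pseudo-inverse of `M` (a `ncol(M) x nrow(M)` matrix).
#' @export
pa_pinv <- function(M, tol = NULL) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("pa_pinv: non-finite entries")
  s <- svd(M)
  if (length(s$d) == 0L || s$d[1] == 0) {
    return(matrix(0, ncol(M), nrow(M)))
  }
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * s$d[1]
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' Matrix exponential (scaling and squaring with a Taylor core)
#'
#' Robust for any square matrix; used for ZOH round trips and for sampling
#' continuous-time models. Not exported as a user-facing numerical tool --
#' it exists so the package has no dependency on an expm-style package.
#'
#' @param M square numeric matrix.
#' @return `exp(M)`.
#' @export
pa_expm <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(n == ncol(M))
  if (!all(is.finite(M))) stop("pa_expm: non-finite entries")
  nrm <- max(rowSums(abs(M)))
  s <- 0L
  if (nrm > 0.5) s <- max(0L, ceiling(log2(nrm / 0.5)))
  A <- M / 2^s
  E <- diag(1, n)
  term <- diag(1, n)
  for (k in 1:24) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Principal matrix logarithm via eigen-decomposition
#'
#' Valid when `M` has no eigenvalue on the closed negative real axis (the
#' standard obstruction to a real ZOH logarithm). Fitted models from decaying
#' oscillatory traces have complex-conjugate eigenvalue pairs, for which the
#' principal logarithm is real.
#'
#' @param M square numeric matrix.
#' @return real matrix `L` with `pa_expm(L)` equal to `M`.
#' @export
pa_logm <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(n == ncol(M))
  e <- eigen(M)
  lam <- e$values
  mod <- Mod(lam)
  if (any(mod < 1e-300)) {
    stop("pa_logm: zero eigenvalue; no ZOH logarithm exists")
  }
  neg_real <- abs(Im(lam)) <= 1e-12 * mod & Re(lam) < 0
  if (any(neg_real)) {
    stop("pa_logm: eigenvalue on the negative real axis; ",
         "the principal ZOH logarithm does not exist")
  }
  V <- e$vectors
  L <- matrix(0i, n, n)
  diag(L) <- log(as.complex(lam))
  out <- V %*% L %*% solve(V)
  if (max(abs(Im(out))) > 1e-6 * max(1, max(abs(Re(out))))) {
    stop("pa_logm: result has a non-negligible imaginary part")
  }
  Re(out)
}

# Orthogonal projection of the rows of X onto the row space of Y:
# X %*% t(Y) %*% pinv(Y %*% t(Y)) %*% Y.
project_rows_onto <- function(X, Y) {
  G <- Y %*% t(Y)
  X %*% t(Y) %*% pa_pinv(G) %*% Y
}

# Trapezoidal integral of y(t) with uniform spacing ts.
trapz <- function(y, ts) {
  n <- length(y)
  if (n < 2L) return(0)
  ts * (sum(y) - (y[1] + y[n]) / 2)
}
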