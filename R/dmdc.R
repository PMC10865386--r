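#' Build snapshot matrices for a single impulse response
#'
#' Splits an M x T response series into the past/future snapshot pair and
#' constructs the input snapshot matrix for an impulse input: the diet vector
#' `z1` acts on the first transition only, all later input columns are zero.
#' The stacked matrix `Omega = [X; Z]` is what the least-squares DMDc fit
#' decomposes.
#'
#' @param series numeric M x T matrix, columns are time points.
#' @param z1 numeric input vector of length l (impulse magnitudes).
#' @return An object of class `snapshot_set` with fields `X` (M x T-1), `Xp`
#'   (M x T-1), `Z` (l x T-1), `Omega` ((M+l) x T-1) and `N = T-1`.
#' @export
build_snapshots <- function(series, z1) {
  series <- as.matrix(series)
  if (ncol(series) < 2L) stopf("need at least two time points (T >= 2)")
  z1 <- as.numeric(z1)
  T_ <- ncol(series)
  X <- series[, -T_, drop = FALSE]
  Xp <- series[, -1L, drop = FALSE]
  Z <- matrix(0, length(z1), T_ - 1L)
  Z[, 1L] <- z1
  structure(list(X = X, Xp = Xp, Z = Z, Omega = rbind(X, Z),
                 M = nrow(series), l = length(z1), N = T_ - 1L,
                 impulse_columns = 1L),
            class = "snapshot_set")
}

#' Leading-V truncated singular value decomposition
#'
#' Thin wrapper around [base::svd()] returning the leading `V` factors with a
#' deterministic sign convention (the largest-magnitude entry of each left
#' singular vector is positive).  The reconstruction `u diag(d) t(w)` is the
#' best rank-V approximation in the Frobenius sense.
#'
#' @param mtx numeric matrix.
#' @param V truncation rank, `1 <= V <= min(dim(mtx))`.
#' @return List with `u`, `d` (length V, non-increasing) and `w`.
#' @export
truncated_svd <- function(mtx, V) {
  mtx <- as.matrix(mtx)
  if (V < 1 || V > min(dim(mtx)))
    stopf("`V` must be between 1 and min(dim) = %d", min(dim(mtx)))
  sv <- svd_sign_fix(svd(mtx))
  list(u = sv$u[, seq_len(V), drop = FALSE], d = sv$d[seq_len(V)],
       w = sv$v[, seq_len(V), drop = FALSE])
}

#' Fit a rank-reduced DMDc operator pair
#'
#' Solves `X' = [A B] [X; Z]` in the least-squares (Frobenius) sense through
#' the truncated-SVD pseudoinverse of `Omega`: `G = X' W S^-1 U^T`, split into
#' the system matrix `A_hat` (M x M) and input matrix `B_hat` (M x l).  With
#' `V = rank(Omega)` this is the minimum-norm least-squares optimum; smaller
#' `V` regularizes the fit.
#'
#' @param s a [build_snapshots()] or [concat_response_snapshots()] object.
#' @param V SVD truncation rank.  Singular values below
#'   `max(dim) * eps * sigma_1` are treated as zero; requesting a rank beyond
#'   the usable rank is an error.
#' @return An object of class `dmdc_model` with fields `A_hat`, `B_hat`,
#'   `rank_V`, `sv_omega` (retained singular values), `sv_full` (full
#'   spectrum) and `fit_residual` (Frobenius norm of `X' - A X - B Z`).
#' @export
fit_dmdc <- function(s, V) {
  stopifnot(inherits(s, c("snapshot_set", "multi_snapshots")))
  sv <- svd_sign_fix(svd(s$Omega))
  usable <- usable_rank(sv$d, dim(s$Omega))
  if (V < 1 || V > usable)
    stopf("rank too high for data; usable rank is %d", usable)
  V <- as.integer(V)
  G <- operator_from_svd(s$Xp, sv, V)
  model_from_G(G, s, V, sv$d)
}

usable_rank <- function(d, dims) {
  tol <- max(dims) * .Machine$double.eps * d[1]
  sum(d > tol)
}

# G_V = Xp %*% w_V %*% diag(1/d_V) %*% t(u_V)
operator_from_svd <- function(Xp, sv, V) {
  w <- sv$v[, seq_len(V), drop = FALSE]
  u <- sv$u[, seq_len(V), drop = FALSE]
  ws <- sweep(w, 2, sv$d[seq_len(V)], "/")
  (Xp %*% ws) %*% t(u)
}

model_from_G <- function(G, s, V, d_full) {
  M <- s$M; l <- s$l
  A_hat <- G[, seq_len(M), drop = FALSE]
  B_hat <- G[, M + seq_len(l), drop = FALSE]
  res <- frob(s$Xp - A_hat %*% s$X - B_hat %*% s$Z)
  structure(list(A_hat = A_hat, B_hat = B_hat, rank_V = V,
                 sv_omega = d_full[seq_len(V)], sv_full = d_full,
                 fit_residual = res, M = M, l = l, N = s$N),
            class = "dmdc_model")
}

#' @export
print.dmdc_model <- function(x, ...) {
  cat(sprintf("<dmdc_model> M = %d states, l = %d inputs, N = %d snapshot columns\n",
              x$M, x$l, x$N))
  cat(sprintf("truncation rank V = %d, one-step fit residual (Frobenius) = %.3g\n",
              x$rank_V, x$fit_residual))
  invisible(x)
}

#' Project a full-state DMDc model onto a latent subspace
#'
#' The latent output map `U_map` is taken as the leading `S` left singular
#' vectors of the future snapshot matrix `X'`; the latent operators are
#' `A_tilde = U^T A_hat U`, `B_tilde = U^T B_hat`.  The latent initial state
#' of a condition is obtained directly from data as `U^T x_1`.
#'
#' @param model a [fit_dmdc()] result.
#' @param Xp the future snapshot matrix the model was fitted to.
#' @param S latent dimension, `S <= rank(Xp)`.
#' @return An object of class `latent_model` with fields `A_tilde` (S x S),
#'   `B_tilde` (S x l), `U_map` (M x S, orthonormal columns) and `S`.
#' @export
reduce_to_latent <- function(model, Xp, S) {
  stopifnot(inherits(model, "dmdc_model"))
  Xp <- as.matrix(Xp)
  sv <- svd_sign_fix(svd(Xp))
  usable <- usable_rank(sv$d, dim(Xp))
  if (S < 1 || S > usable)
    stopf("latent dimension S exceeds rank(X') = %d", usable)
  S <- as.integer(S)
  U <- sv$u[, seq_len(S), drop = FALSE]
  structure(list(A_tilde = crossprod(U, model$A_hat %*% U),
                 B_tilde = crossprod(U, model$B_hat),
                 U_map = U, S = S, sv_xp = sv$d,
                 initial_states = list()),
            class = "latent_model")
}

#' Simulate a discrete linear dynamical system
#'
#' Rolls `x_{t+1} = A x_t + B z_t` forward from `x1`, returning the state
#' trajectory as columns `x_1 .. x_T`.  Works identically for full-state and
#' latent systems.
#'
#' @param A system matrix (n x n).
#' @param B input matrix (n x l); may be NULL when there is no input.
#' @param x1 initial state (length n).
#' @param inputs l x (T-1) input matrix (defaults to zero input).
#' @param T_ horizon (number of time points returned).
#' @return n x T trajectory matrix.
#' @export
simulate_lds <- function(A, B = NULL, x1, inputs = NULL, T_) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stopf("`A` must be square")
  x1 <- as.numeric(x1)
  if (length(x1) != n) stopf("`x1` has length %d, expected %d", length(x1), n)
  if (T_ < 1) stopf("horizon must be >= 1")
  if (!is.null(B)) {
    B <- as.matrix(B)
    if (nrow(B) != n) stopf("`B` must have %d rows", n)
    if (is.null(inputs)) inputs <- matrix(0, ncol(B), max(T_ - 1L, 0L))
    inputs <- as.matrix(inputs)
    if (nrow(inputs) != ncol(B) || ncol(inputs) < T_ - 1L)
      stopf("`inputs` must be l x (T-1) = %d x %d", ncol(B), T_ - 1L)
  }
  out <- matrix(0, n, T_)
  out[, 1L] <- x1
  for (t in seq_len(T_ - 1L)) {
    out[, t + 1L] <- A %*% out[, t]
    if (!is.null(B)) out[, t + 1L] <- out[, t + 1L] + B %*% inputs[, t]
  }
  out
}

#' Impulse input matrix
#'
#' The meal enters the system once: `z1` occupies the first input column and
#' every later column is zero.
#'
#' @param z1 input vector of length l.
#' @param T_ horizon; the returned matrix has T-1 columns.
#' @return l x (T-1) matrix.
#' @export
impulse_inputs <- function(z1, T_) {
  Z <- matrix(0, length(z1), T_ - 1L)
  Z[, 1L] <- as.numeric(z1)
  Z
}
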