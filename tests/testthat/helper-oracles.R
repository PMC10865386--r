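# Shared fixtures and independent oracles used across the suite.

# Random stable linear system with impulse responses; the generator is the
# recovery oracle for the DMDc fits.
rand_lds <- function(M, l, rho = 0.8, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(M * M), M, M)
    A <- A * (rho / max(Mod(eigen(A, only.values = TRUE)$values)))
    B <- matrix(rnorm(M * l), M, l)
    list(A = A, B = B)
  })
}

# Noiseless impulse-response observations of a known system.
lds_observations <- function(sys, diets, T_, x1 = NULL) {
  lapply(seq_len(ncol(diets)), function(d) {
    x0 <- x1 %||% rep(0, nrow(sys$A))
    list(series = simulate_lds(sys$A, sys$B, x0,
                               impulse_inputs(diets[, d], T_), T_),
         z1 = diets[, d])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent least-squares route: normal equations for X' = G Omega
# (valid when Omega has full row rank).
ls_normal_equations <- function(Xp, Omega) {
  t(solve(tcrossprod(Omega), Omega %*% t(Xp)))
}

# Brute-force restatement of the log-spaced index rule: endpoint-inclusive
# log grid on 1..T, rounded, duplicates resolved by stepping to the next
# unused index.
oracle_log_indices <- function(T_, n_out) {
  raw <- round(exp(seq(0, log(T_), length.out = n_out)))
  used <- integer(0)
  for (v in raw) {
    while (v %in% used) v <- v + 1L
    used <- c(used, v)
  }
  as.integer(used)
}

# Small complete long-format tensor file written through the package writer.
write_tensor_fixture <- function(path, M = 2, T_ = 3, I = 2, D = 2, seed = 42) {
  arr <- withr::with_seed(seed,
    array(round(rnorm(M * T_ * I * D), 3), c(M, T_, I, D)))
  x <- response_tensor(arr)
  write_tensor_long(x, path, sidecar = FALSE)
  x
}

# Planted rank-F four-way tensor from known factors.
planted_cp_tensor <- function(dims, F_, seed = 1) {
  withr::with_seed(seed, {
    fac <- lapply(dims, function(n) matrix(rnorm(n * F_), n, F_))
    arr <- array(0, dims)
    for (f in seq_len(F_)) {
      arr <- arr + outer(outer(fac[[1]][, f], fac[[2]][, f]),
                         outer(fac[[3]][, f], fac[[4]][, f]))
    }
    list(tensor = arr, factors = fac)
  })
}

# Congruence (absolute cosine) between matched factor columns after the best
# permutation, product over the given modes.
factor_congruence <- function(est, truth) {
  F_ <- ncol(est[[1]])
  unit <- function(m) sweep(m, 2, sqrt(colSums(m^2)), "/")
  cong <- Reduce(`*`, Map(function(e, t) abs(crossprod(unit(e), unit(t))),
                          est, truth))
  best <- 0
  for (p in perms_of(F_)) {
    best <- max(best, min(cong[cbind(seq_len(F_), p)]))
  }
  best
}

perms_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perms_of(k - 1L)) for (pos in 0:(k - 1L))
    out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}
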