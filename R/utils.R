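# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded operations are pure functions
#' of their inputs and never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive n reproducible child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

frob <- function(m) sqrt(sum(m^2))

spectral_radius <- function(a) max(Mod(eigen(a, only.values = TRUE)$values))

# Deterministic sign convention: the largest-magnitude entry of each left
# singular vector is made positive, so factorizations reproduce across
# platforms and BLAS builds.
svd_sign_fix <- function(sv) {
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  sv
}

# Locale-independent sort for axis labels.
radix_sort <- function(x) sort(x, method = "radix")

# Format a double so that as.numeric() recovers it bit-exactly.
num_tag <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
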