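#' Concatenate several impulse responses into one snapshot set
#'
#' Column-wise block concatenation of the snapshot matrices of D responses
#' (e.g. the D diets of one individual, or all observations of a pooled fit).
#' Each block contributes T-1 columns and its own impulse column carrying that
#' response's diet vector.
#'
#' @param responses list of `list(series = M x T matrix, z1 = input vector)`;
#'   all responses must share M, T and l.
#' @return An object of class `multi_snapshots`: fields `X`, `Xp` (M x
#'   D(T-1)), `Z`, `Omega`, `diet_boundaries` (list of column ranges) and
#'   `impulse_columns`.
#' @export
concat_response_snapshots <- function(responses) {
  if (!length(responses)) stopf("need at least one response")
  parts <- lapply(responses, function(r) build_snapshots(r$series, r$z1))
  M <- parts[[1]]$M; l <- parts[[1]]$l; n <- parts[[1]]$N
  ok <- vapply(parts, function(p) p$M == M && p$l == l && p$N == n, logical(1))
  if (!all(ok)) stopf("all responses must share M, T and input length l")
  X <- do.call(cbind, lapply(parts, `[[`, "X"))
  Xp <- do.call(cbind, lapply(parts, `[[`, "Xp"))
  Z <- do.call(cbind, lapply(parts, `[[`, "Z"))
  k <- length(parts)
  structure(list(X = X, Xp = Xp, Z = Z, Omega = rbind(X, Z),
                 M = M, l = l, N = k * n,
                 diet_boundaries = lapply(seq_len(k) - 1L,
                                          function(j) j * n + seq_len(n)),
                 impulse_columns = (seq_len(k) - 1L) * n + 1L),
            class = "multi_snapshots")
}

#' Fit one individual's latent linear dynamics from all diets
#'
#' Runs the DMDc fit on the diet-concatenated snapshots, then projects onto
#' the individual's own latent basis (leading left singular vectors of the
#' concatenated future snapshots).  Each diet receives a distinct latent
#' initial state `x1_tilde = U^T x1` while sharing the same operators.
#'
#' @param ms a [concat_response_snapshots()] object.
#' @param V SVD truncation rank for the operator fit.
#' @param S latent dimension.
#' @param individual_id optional label.
#' @return An object of class `individual_latent_model` with `A_tilde`,
#'   `B_tilde`, `U_map`, per-diet `initial_states` (S x D) and the full-state
#'   `model`.
#' @export
fit_individual <- function(ms, V, S, individual_id = "i1") {
  stopifnot(inherits(ms, "multi_snapshots"))
  model <- fit_dmdc(ms, V)
  lat <- reduce_to_latent(model, ms$Xp, S)
  x1 <- ms$X[, ms$impulse_columns, drop = FALSE]
  init <- crossprod(lat$U_map, x1)
  colnames(init) <- names(ms$diet_boundaries) %||% NULL
  structure(list(individual_id = individual_id,
                 A_tilde = lat$A_tilde, B_tilde = lat$B_tilde,
                 U_map = lat$U_map, S = lat$S,
                 initial_states = init, model = model,
                 basis_provenance = NULL),
            class = "individual_latent_model")
}

#' Shared latent basis across all individuals
#'
#' Computes the SVD of `X_tot`, the M x (T*D*I) column-wise concatenation of
#' every individual's diet-concatenated response, and retains the leading `S`
#' left singular vectors as the output map shared by the whole population.
#' Sharing one basis is what makes latent state trajectories comparable
#' between individuals.  The full singular-value spectrum is kept for scree
#' analysis.
#'
#' @param x a [response_tensor()].
#' @param S retained dimension, `S <= rank(X_tot)`.
#' @return An object of class `shared_basis` with `U_tot` (M x S, orthonormal
#'   columns), `singular_values` (full spectrum) and `S`.
#' @export
compute_shared_basis <- function(x, S) {
  stopifnot(inherits(x, "response_tensor"))
  Xtot <- flatten_tensor(x)
  sv <- svd_sign_fix(svd(Xtot))
  usable <- usable_rank(sv$d, dim(Xtot))
  if (S < 1 || S > usable)
    stopf("S exceeds rank(X_tot) = %d", usable)
  S <- as.integer(S)
  structure(list(U_tot = sv$u[, seq_len(S), drop = FALSE],
                 singular_values = sv$d, S = S,
                 provenance = list(M = dim(x)[1],
                                   sv_head = sv$d[seq_len(min(5, length(sv$d)))])),
            class = "shared_basis")
}

# M x (T*D*I) matrix: per individual, per diet, the M x T slice (time fastest,
# then diet, individual slowest).
flatten_tensor <- function(x) {
  a <- aperm(x$values, c(1, 2, 4, 3))
  dim(a) <- c(dim(x)[1], prod(dim(x)[-1]))
  a
}

#' @export
print.shared_basis <- function(x, ...) {
  cat(sprintf("<shared_basis> %d metabolites -> %d latent states\n",
              nrow(x$U_tot), x$S))
  cat("leading singular values:",
      paste(signif(utils::head(x$singular_values, 6), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit per-individual latent dynamics in a shared basis
#'
#' Projects each individual's diet-concatenated snapshots onto the shared
#' basis (`X_tilde = U_tot^T X`) and runs the DMDc least-squares fit entirely
#' in the S-dimensional latent space, giving per-individual operators
#' `A_tilde_i` (S x S), `B_tilde_i` (S x l) and per-diet latent initial
#' states.  Because the output map is shared, the resulting latent
#' trajectories are directly comparable across individuals.
#'
#' @param x a baseline-subtracted [response_tensor()].
#' @param diets a [diet_input_matrix()] matching the tensor's diets.
#' @param basis a [compute_shared_basis()] result.
#' @param V truncation rank for the per-individual latent fit (defaults to
#'   the usable rank of each individual's latent `Omega`).
#' @return List of `individual_latent_model` objects (class
#'   `pdmdc_population`).
#' @export
fit_shared_latent <- function(x, diets, basis, V = NULL) {
  stopifnot(inherits(x, "response_tensor"), inherits(basis, "shared_basis"))
  check_diets(x, diets)
  if (!"baseline_subtracted" %in% x$preprocessing_log)
    warning("tensor does not appear to be baseline-subtracted", call. = FALSE)
  dm <- dim(x)
  U <- basis$U_tot
  models <- vector("list", dm[3])
  for (i in seq_len(dm[3])) {
    responses <- lapply(seq_len(dm[4]), function(d)
      list(series = crossprod(U, x$values[, , i, d]),
           z1 = diets$inputs[, d]))
    ms <- concat_response_snapshots(responses)
    Vi <- V %||% usable_rank(svd(ms$Omega, nu = 0, nv = 0)$d, dim(ms$Omega))
    model <- tryCatch(fit_dmdc(ms, Vi),
                      error = function(e) stopf("individual %s: %s",
                                                x$individual_ids[i],
                                                conditionMessage(e)))
    init <- ms$X[, ms$impulse_columns, drop = FALSE]
    colnames(init) <- x$diet_ids
    models[[i]] <- structure(
      list(individual_id = x$individual_ids[i],
           A_tilde = model$A_hat, B_tilde = model$B_hat,
           U_map = U, S = basis$S,
           initial_states = init, model = model,
           basis_provenance = basis$provenance),
      class = "individual_latent_model")
  }
  names(models) <- x$individual_ids
  structure(models, class = "pdmdc_population", basis = basis)
}

check_diets <- function(x, diets) {
  stopifnot(inherits(diets, "diet_input_matrix"))
  if (!identical(diets$diet_ids, x$diet_ids))
    stopf("diet ids of tensor (%s) and diet matrix (%s) disagree",
          paste(x$diet_ids, collapse = ","),
          paste(diets$diet_ids, collapse = ","))
  invisible(TRUE)
}

#' Pooled full-state fit over many observations
#'
#' Concatenates all training observations (each an impulse response with its
#' diet vector) into one snapshot set and fits a single full-state
#' rank-reduced model.  Prediction of unseen diets deliberately stays at full
#' state dimension; latent projection is reserved for metabotyping.
#'
#' @param observations list of `list(series, z1)` as in
#'   [concat_response_snapshots()].
#' @param V truncation rank.
#' @return A `dmdc_model`.
#' @export
fit_pooled <- function(observations, V) {
  ms <- concat_response_snapshots(observations)
  fit_dmdc(ms, V)
}

#' Predict the response to a new diet from baseline and diet composition
#'
#' In baseline-subtracted coordinates the pre-meal state is the zero vector,
#' so the whole predicted deviation is driven by the impulse `B_hat z1`; the
#' measured baseline only re-enters when reporting in original units.
#'
#' @param model a fitted `dmdc_model`.
#' @param z1 diet input vector (length l).
#' @param T_ prediction horizon (number of time points).
#' @param baseline_state optional length-M baseline to add back for reporting.
#' @param scales optional length-M standardization scales to undo.
#' @return M x T predicted response matrix.
#' @export
predict_response <- function(model, z1, T_, baseline_state = NULL,
                             scales = NULL) {
  stopifnot(inherits(model, "dmdc_model"))
  z1 <- as.numeric(z1)
  if (length(z1) != model$l)
    stopf("diet vector has length %d, model expects %d", length(z1), model$l)
  pred <- simulate_lds(model$A_hat, model$B_hat, rep(0, model$M),
                       impulse_inputs(z1, T_), T_)
  if (!is.null(scales)) pred <- pred * scales
  if (!is.null(baseline_state)) pred <- pred + baseline_state
  pred
}

#' Expand a tensor into per-(individual, diet) observations
#'
#' @param x a [response_tensor()].
#' @param diets a matching [diet_input_matrix()].
#' @param keys optional data frame with columns `individual`, `diet`
#'   (indices or ids) selecting a subset; defaults to all I x D observations.
#' @return List of `list(series, z1, individual, diet)`.
#' @export
tensor_observations <- function(x, diets, keys = NULL) {
  stopifnot(inherits(x, "response_tensor"))
  check_diets(x, diets)
  if (is.null(keys))
    keys <- expand.grid(individual = x$individual_ids, diet = x$diet_ids,
                        stringsAsFactors = FALSE)
  ii <- if (is.numeric(keys$individual)) keys$individual
        else match(keys$individual, x$individual_ids)
  dd <- if (is.numeric(keys$diet)) keys$diet else match(keys$diet, x$diet_ids)
  if (anyNA(ii) || anyNA(dd)) stopf("unknown individual or diet in keys")
  lapply(seq_len(nrow(keys)), function(k)
    list(series = x$values[, , ii[k], dd[k]],
         z1 = diets$inputs[, dd[k]],
         individual = x$individual_ids[ii[k]], diet = x$diet_ids[dd[k]]))
}
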