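#' Fit a parametric DMDc model to a response tensor
#'
#' The main fitting front-end.  Three fitting modes cover the two uses of the
#' method:
#'
#' * `"pooled"` — all (individual, diet) observations are concatenated and a
#'   single full-state operator pair is fitted; this is the prediction model
#'   (responses to unseen diets from baseline + diet composition).
#' * `"shared"` — a shared orthonormal output map is computed from all data
#'   and per-individual latent operators are fitted in that basis; this is
#'   the metabotyping model (comparable latent state trajectories).
#' * `"individual"` — per-individual fits with per-individual latent bases.
#'
#' @param x a preprocessed (typically baseline-subtracted)
#'   [response_tensor()].
#' @param diets a [diet_input_matrix()] matching the tensor.
#' @param method fitting mode, see above.
#' @param rank SVD truncation rank V for the operator fit; defaults to the
#'   usable rank of the snapshot stack.
#' @param latent_dim latent dimension S; for `"shared"` it defaults to the
#'   scree-inflection suggestion, for `"individual"` to `rank`.
#' @return An object of class `pdmdc`, with methods for `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `simulate` and `plot`.
#' @examples
#' pop <- synthetic_preset("measured-like", seed = 1)
#' x <- subtract_baseline(pop$tensor)
#' fit <- pdmdc(x, pop$diets, method = "pooled")
#' print(fit)
#' pred <- predict(fit, diet = pop$diets$inputs[, 1], horizon = 8)
#' @export
pdmdc <- function(x, diets, method = c("pooled", "shared", "individual"),
                  rank = NULL, latent_dim = NULL) {
  stopifnot(inherits(x, "response_tensor"))
  method <- match.arg(method)
  check_diets(x, diets)
  dm <- dim(x)
  obj <- list(method = method, dims = dm, diets = diets,
              metabolite_ids = x$metabolite_ids, diet_ids = x$diet_ids,
              individual_ids = x$individual_ids,
              time_points = x$time_points,
              preprocessing_log = x$preprocessing_log,
              call = match.call())
  if (method == "pooled") {
    obs <- tensor_observations(x, diets)
    ms <- concat_response_snapshots(lapply(obs, `[`, c("series", "z1")))
    V <- rank %||% usable_rank(svd(ms$Omega, nu = 0, nv = 0)$d, dim(ms$Omega))
    obj$model <- fit_dmdc(ms, V)
    obj$snapshots <- ms
    obj$observations <- obs
    obj$rank <- V
  } else if (method == "shared") {
    S <- latent_dim %||% scree_inflection(
      svd(flatten_tensor(x), nu = 0, nv = 0)$d)
    obj$basis <- compute_shared_basis(x, S)
    obj$individuals <- fit_shared_latent(x, diets, obj$basis, V = rank)
    obj$latent_dim <- S
    obj$rank <- rank %||% obj$individuals[[1]]$model$rank_V
    obj$trajectories <- extract_state_trajectories(obj$individuals, diets,
                                                   T_ = dm[2])
  } else {
    obj$individuals <- lapply(seq_len(dm[3]), function(i) {
      responses <- lapply(seq_len(dm[4]), function(d)
        list(series = x$values[, , i, d], z1 = diets$inputs[, d]))
      ms <- concat_response_snapshots(responses)
      V <- rank %||% usable_rank(svd(ms$Omega, nu = 0, nv = 0)$d, dim(ms$Omega))
      fit_individual(ms, V, latent_dim %||% V, x$individual_ids[i])
    })
    names(obj$individuals) <- x$individual_ids
    obj$rank <- rank
    obj$latent_dim <- latent_dim
  }
  structure(obj, class = "pdmdc")
}

#' @export
print.pdmdc <- function(x, ...) {
  dm <- x$dims
  cat(sprintf("Parametric DMDc fit (%s)\n", x$method))
  cat(sprintf("  data: %d metabolites, %d time points, %d individuals, %d diets\n",
              dm[1], dm[2], dm[3], dm[4]))
  if (x$method == "pooled") {
    cat(sprintf("  truncation rank V = %d (usable rank %d), fit residual = %.4g\n",
                x$model$rank_V, length(x$model$sv_full[x$model$sv_full > 0]),
                x$model$fit_residual))
  } else if (x$method == "shared") {
    cat(sprintf("  shared latent dimension S = %d; %d per-individual latent fits\n",
                x$latent_dim, length(x$individuals)))
  } else {
    cat(sprintf("  %d per-individual fits\n", length(x$individuals)))
  }
  invisible(x)
}

#' @export
summary.pdmdc <- function(object, ...) {
  out <- list(method = object$method, dims = object$dims, rank = object$rank)
  if (object$method == "pooled") {
    out$fit_residual <- object$model$fit_residual
    out$singular_values <- object$model$sv_full
    tr <- vapply(object$observations, function(o) {
      pred <- predict_response(object$model, o$z1, ncol(o$series))
      1 - sum((pred - o$series)^2) / sum((o$series - mean(o$series))^2)
    }, numeric(1))
    out$training_r2 <- tr
  } else if (object$method %in% c("shared", "individual")) {
    out$latent_dim <- object$latent_dim
    out$spectral_radii <- vapply(object$individuals,
                                 function(m) spectral_radius(m$A_tilde),
                                 numeric(1))
    if (!is.null(object$basis))
      out$singular_values <- object$basis$singular_values
  }
  structure(out, class = "summary.pdmdc")
}

#' @export
print.summary.pdmdc <- function(x, ...) {
  cat(sprintf("pDMDc %s fit; rank V = %s\n", x$method,
              x$rank %||% "auto"))
  if (!is.null(x$training_r2)) {
    cat(sprintf("  training rollout R2 over %d observations: mean %.3f (range %.3f..%.3f)\n",
                length(x$training_r2), mean(x$training_r2),
                min(x$training_r2), max(x$training_r2)))
  }
  if (!is.null(x$spectral_radii))
    cat(sprintf("  per-individual spectral radii: %.3f .. %.3f\n",
                min(x$spectral_radii), max(x$spectral_radii)))
  if (!is.null(x$singular_values))
    cat("  leading singular values:",
        paste(signif(utils::head(x$singular_values, 6), 4), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.pdmdc <- function(object, ...) {
  if (object$method == "pooled")
    return(list(A = object$model$A_hat, B = object$model$B_hat))
  lapply(object$individuals,
         function(m) list(A = m$A_tilde, B = m$B_tilde, U = m$U_map))
}

#' Predict metabolite responses to (possibly unseen) diets
#'
#' @param object a pooled-method [pdmdc()] fit.
#' @param diet input vector of length l, or l x K matrix of diets.
#' @param horizon number of time points (defaults to the training T).
#' @param baseline optional length-M pre-meal baseline added back for
#'   reporting in original units.
#' @param ... unused.
#' @return M x horizon matrix, or a list of them for multiple diets.
#' @export
predict.pdmdc <- function(object, diet, horizon = NULL, baseline = NULL, ...) {
  if (object$method != "pooled")
    stopf("prediction of unseen diets uses the pooled full-state fit")
  horizon <- horizon %||% object$dims[2]
  diet <- if (is.matrix(diet)) diet else matrix(diet, ncol = 1)
  preds <- lapply(seq_len(ncol(diet)), function(k)
    predict_response(object$model, diet[, k], horizon,
                     baseline_state = baseline))
  if (length(preds) == 1L) preds[[1]] else preds
}

#' @export
residuals.pdmdc <- function(object, ...) {
  if (object$method == "pooled") {
    m <- object$model; s <- object$snapshots
    return(s$Xp - m$A_hat %*% s$X - m$B_hat %*% s$Z)
  }
  vapply(object$individuals, function(im) im$model$fit_residual, numeric(1))
}

#' Roll out the fitted dynamics for every training condition
#'
#' For a pooled fit, reconstructs every training observation from its impulse
#' alone; for a shared fit, returns the latent state trajectory array.
#'
#' @param object a [pdmdc()] fit.
#' @param nsim,seed unused (the rollout is deterministic); present for
#'   compatibility with [stats::simulate()].
#' @param ... unused.
#' @export
simulate.pdmdc <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$method == "pooled") {
    out <- lapply(object$observations, function(o)
      predict_response(object$model, o$z1, ncol(o$series)))
    names(out) <- vapply(object$observations,
                         function(o) paste(o$individual, o$diet, sep = ":"),
                         character(1))
    return(out)
  }
  if (!is.null(object$trajectories)) return(object$trajectories)
  stopf("simulate() supports pooled and shared fits")
}

#' Plot observed versus fitted trajectories
#'
#' @param x a pooled [pdmdc()] fit.
#' @param metabolites indices of metabolites to show (default first 6).
#' @param observation index of the training observation to display.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pdmdc <- function(x, metabolites = NULL, observation = 1L, ...) {
  if (x$method != "pooled") stopf("plotting is provided for pooled fits")
  o <- x$observations[[observation]]
  pred <- predict_response(x$model, o$z1, ncol(o$series))
  metabolites <- metabolites %||% seq_len(min(6L, nrow(o$series)))
  old <- graphics::par(mfrow = c(2, ceiling(length(metabolites) / 2)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  tp <- x$time_points
  for (m in metabolites) {
    graphics::plot(tp, o$series[m, ], pch = 16, xlab = "time", ylab = "",
                   main = x$metabolite_ids[m], ...)
    graphics::lines(tp, pred[m, ], col = "red")
  }
  invisible(x)
}
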