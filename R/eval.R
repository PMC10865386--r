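#' Random train/validation/test split of observations
#'
#' Observations (individual, diet) are randomly permuted under the given seed
#' and allocated by floor arithmetic with the remainder assigned to the
#' training set, so 51 observations at 60/20/20 give 31/10/10.
#'
#' @param keys data frame of observation keys (one row per observation), or an
#'   integer count.
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return An object of class `observation_split` with integer index vectors
#'   `train`, `validation`, `test`.
#' @export
split_observations <- function(keys, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- if (is.data.frame(keys)) nrow(keys) else as.integer(keys)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stopf("`fractions` must be three numbers summing to 1")
  if (n < 1L) stopf("no observations to split")
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  sizes <- c(n_train, n_val, n_test)
  empty <- fractions > 0 & sizes == 0
  if (any(empty))
    stopf("split produced an empty %s set",
          c("training", "validation", "test")[which(empty)[1]])
  structure(list(train = sort(perm[seq_len(n_train)]),
                 validation = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[n_train + n_val + seq_len(n_test)]),
                 fractions = fractions, seed = seed, n = n),
            class = "observation_split")
}

#' Coefficient of determination over a vectorized test tensor
#'
#' `R2 = 1 - sum((pred - data)^2) / sum((grand_mean - data)^2)`, where the
#' grand mean is taken over all entries of the observed test tensor.  Equals 1
#' for a perfect prediction, 0 for the grand-mean predictor, and can be
#' negative.
#'
#' @param pred,data numeric arrays of identical shape.
#' @return Scalar R-squared.
#' @export
r_squared <- function(pred, data) {
  if (!identical(dim(pred) %||% length(pred), dim(data) %||% length(data)))
    stopf("`pred` and `data` must have identical shape")
  ss_tot <- sum((mean(data) - data)^2)
  if (ss_tot <= 0) stopf("constant data tensor: R-squared undefined")
  1 - sum((pred - data)^2) / ss_tot
}

rollout_rmse <- function(model, observations) {
  se <- 0; n <- 0
  for (o in observations) {
    pred <- simulate_lds(model$A_hat, model$B_hat, o$series[, 1],
                         impulse_inputs(o$z1, ncol(o$series)), ncol(o$series))
    se <- se + sum((pred - o$series)^2)
    n <- n + length(o$series)
  }
  sqrt(se / n)
}

#' Select the SVD truncation rank by the 30% validation-RMSE rule
#'
#' Iterates the truncation rank V over an ascending grid, fitting on the
#' training observations and measuring full-trajectory rollout RMSE on both
#' sets.  Scanning stops at the first V where the validation RMSE deviates
#' from the training RMSE by more than `tol` (relative); among the visited
#' ranks, the model with the lowest validation RMSE is returned, with
#' near-ties (within `tie_tol` relative) broken in favour of the smallest
#' rank — the validation curve is typically flat beyond the true rank, and
#' parsimony keeps the selection stable there.
#'
#' @param train_obs,val_obs lists of `list(series, z1)` observations.
#' @param V_grid ascending integer grid (default `1:rank(Omega)`).
#' @param tol relative deviation triggering the stop (default 0.30).
#' @param tie_tol relative tolerance within which validation RMSEs count as
#'   tied (default 0.01).
#' @return List with `model` (refit at the selected rank), `V`, a data frame
#'   `path` of visited ranks and RMSEs, and `warning` (TRUE when the rule
#'   rejected every rank and the V = grid minimum model is returned).
#' @export
select_rank <- function(train_obs, val_obs, V_grid = NULL, tol = 0.30,
                        tie_tol = 0.01) {
  ms <- concat_response_snapshots(lapply(train_obs, `[`, c("series", "z1")))
  sv <- svd_sign_fix(svd(ms$Omega))
  usable <- usable_rank(sv$d, dim(ms$Omega))
  V_grid <- V_grid %||% seq_len(usable)
  if (!length(V_grid)) stopf("empty rank grid")
  if (is.unsorted(V_grid)) stopf("`V_grid` must be ascending")
  V_grid <- V_grid[V_grid <= usable]
  if (!length(V_grid)) stopf("rank grid entirely above usable rank %d", usable)
  visited <- integer(0); rmse_tr <- numeric(0); rmse_va <- numeric(0)
  stopped <- FALSE
  for (V in V_grid) {
    G <- operator_from_svd(ms$Xp, sv, V)
    model <- model_from_G(G, ms, V, sv$d)
    visited <- c(visited, V)
    rmse_tr <- c(rmse_tr, rollout_rmse(model, train_obs))
    rmse_va <- c(rmse_va, rollout_rmse(model, val_obs))
    k <- length(visited)
    if (rmse_tr[k] > 0 &&
        abs(rmse_va[k] - rmse_tr[k]) / rmse_tr[k] > tol) {
      stopped <- TRUE
      break
    }
  }
  warn <- stopped && length(visited) == 1L
  best <- which(rmse_va <= min(rmse_va) * (1 + tie_tol))[1]
  V_best <- visited[best]
  list(model = model_from_G(operator_from_svd(ms$Xp, sv, V_best), ms,
                            V_best, sv$d),
       V = V_best,
       path = data.frame(V = visited, rmse_train = rmse_tr,
                         rmse_validation = rmse_va),
       warning = warn)
}

predict_test_r2 <- function(model, test_obs) {
  pred <- lapply(test_obs, function(o)
    simulate_lds(model$A_hat, model$B_hat, o$series[, 1],
                 impulse_inputs(o$z1, ncol(o$series)), ncol(o$series)))
  r_squared(do.call(cbind, pred), do.call(cbind, lapply(test_obs, `[[`, "series")))
}

#' Resampled prediction experiment
#'
#' The full evaluation cycle: randomly permute the (individual, diet)
#' observations, split 60/20/20, select the rank by the 30% rule, fit the
#' pooled model and measure R-squared on the held-out test observations —
#' repeated `n_iter` times (resampling without replacement) and averaged.
#'
#' @param x a preprocessed [response_tensor()].
#' @param diets a matching [diet_input_matrix()].
#' @param n_iter number of resampling iterations (default 100).
#' @param seed master seed; every iteration derives its own child seed.
#' @param fractions split fractions (default 0.6/0.2/0.2).
#' @param tol rank-selection deviation tolerance.
#' @param V_grid optional rank grid passed to [select_rank()].
#' @return An `experiment_report`: data frame `iterations` (r2, selected
#'   rank, seed), `mean_r2` and the call parameters.
#' @export
resampling_experiment <- function(x, diets, n_iter = 100L, seed = 1L,
                                  fractions = c(0.6, 0.2, 0.2), tol = 0.30,
                                  V_grid = NULL) {
  obs <- tensor_observations(x, diets)
  seeds <- derive_seeds(seed, n_iter)
  r2 <- numeric(n_iter); rank_sel <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    sp <- split_observations(length(obs), fractions, seed = seeds[it])
    sel <- select_rank(obs[sp$train], obs[sp$validation], V_grid = V_grid,
                       tol = tol)
    r2[it] <- predict_test_r2(sel$model, obs[sp$test])
    rank_sel[it] <- sel$V
  }
  structure(list(iterations = data.frame(iteration = seq_len(n_iter), r2 = r2,
                                         rank = rank_sel, seed = seeds),
                 mean_r2 = mean(r2), seed = seed, fractions = fractions,
                 tol = tol, n = length(obs)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d iterations, mean R2 = %.4f\n",
              nrow(x$iterations), x$mean_r2))
  if (!is.null(x$diet_counts)) {
    cat("diet-count grid:", paste(x$diet_counts, collapse = ", "), "\n")
    cat("mean R2 per count:",
        paste(sprintf("%.3f", x$mean_r2_per_count), collapse = ", "), "\n")
  } else {
    cat(sprintf("selected ranks: %s\n",
                paste(sort(unique(x$iterations$rank)), collapse = ", ")))
  }
  invisible(x)
}

#' Prediction accuracy as a function of training diet count
#'
#' Emulates the increasing-diet experiment: a fixed held-out set of
#' `n_test_diets` diets (all individuals) is predicted by pooled models
#' trained on a growing number of diets.  For each count, the observations of
#' the training diets are scrambled and split into train/validation (`reps`
#' scrambles), the rank is selected by the 30% rule, and test R-squared is
#' recorded.
#'
#' @param x a preprocessed [response_tensor()] whose diet axis holds the full
#'   diet pool.
#' @param diets a matching [diet_input_matrix()].
#' @param diet_counts integer grid of training diet counts (default 3:40).
#' @param n_test_diets size of the fixed held-out diet set (default 50).
#' @param reps scrambles per count (default 5).
#' @param seed master seed.
#' @param val_fraction fraction of training-diet observations used for
#'   validation (default 0.2).
#' @param tol rank-selection tolerance.
#' @return An `experiment_report` with per-(count, rep) R-squared, the diet
#'   count grid and per-count means.
#' @export
diet_count_experiment <- function(x, diets, diet_counts = 3:40,
                                  n_test_diets = 50L, reps = 5L, seed = 1L,
                                  val_fraction = 0.2, tol = 0.30) {
  D <- dim(x)[4]
  if (max(diet_counts) + n_test_diets > D)
    stopf("need at least %d diets, tensor has %d",
          max(diet_counts) + n_test_diets, D)
  seeds <- derive_seeds(seed, 2L + reps)
  diet_perm <- with_seed(seeds[1], sample.int(D))
  test_diets <- diet_perm[seq_len(n_test_diets)]
  pool <- diet_perm[n_test_diets + seq_len(D - n_test_diets)]
  test_obs <- tensor_observations(
    x, diets, expand.grid(individual = seq_len(dim(x)[3]), diet = test_diets))
  rows <- list()
  for (r in seq_len(reps)) {
    rep_seeds <- derive_seeds(seeds[2L + r], length(diet_counts))
    for (ci in seq_along(diet_counts)) {
      k <- diet_counts[ci]
      train_diets <- pool[seq_len(k)]
      obs <- tensor_observations(
        x, diets,
        expand.grid(individual = seq_len(dim(x)[3]), diet = train_diets))
      sp <- split_observations(length(obs),
                               c(1 - val_fraction, val_fraction, 0),
                               seed = rep_seeds[ci])
      sel <- select_rank(obs[sp$train], obs[sp$validation], tol = tol)
      rows[[length(rows) + 1L]] <-
        data.frame(diet_count = k, rep = r, r2 = predict_test_r2(sel$model, test_obs),
                   rank = sel$V)
    }
  }
  tab <- do.call(rbind, rows)
  means <- tapply(tab$r2, tab$diet_count, mean)
  structure(list(iterations = tab,
                 mean_r2 = mean(tab$r2),
                 diet_counts = as.integer(names(means)),
                 mean_r2_per_count = as.numeric(means),
                 test_diets = test_diets, seed = seed, n = length(test_obs)),
            class = "experiment_report")
}
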