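#' Latent state trajectories for every individual and diet
#'
#' Rolls each individual's latent model forward from its per-diet initial
#' state with that diet's impulse, returning the full (state, time,
#' individual, diet) trajectory array used for metabotyping.
#'
#' @param models a `pdmdc_population` (or list of `individual_latent_model`).
#' @param diets a [diet_input_matrix()]; its columns must match the per-diet
#'   initial states stored in the models.
#' @param T_ trajectory horizon (number of time points).
#' @return An object of class `state_trajectory_set`: array `trajectories`
#'   (S x T x I x D) plus basis provenance.
#' @export
extract_state_trajectories <- function(models, diets, T_) {
  stopifnot(length(models) >= 1L, inherits(diets, "diet_input_matrix"))
  S <- models[[1]]$S
  prov <- models[[1]]$basis_provenance
  for (m in models) {
    if (m$S != S || !identical(m$basis_provenance, prov))
      stopf("individual %s was fitted in a different basis", m$individual_id)
  }
  D <- ncol(diets$inputs)
  I <- length(models)
  arr <- array(NA_real_, c(S, T_, I, D),
               dimnames = list(paste0("state", seq_len(S)), NULL,
                               vapply(models, `[[`, "", "individual_id"),
                               diets$diet_ids))
  for (i in seq_len(I)) {
    m <- models[[i]]
    if (ncol(m$initial_states) != D)
      stopf("individual %s has %d initial states but %d diets supplied",
            m$individual_id, ncol(m$initial_states), D)
    for (d in seq_len(D)) {
      arr[, , i, d] <- simulate_lds(m$A_tilde, m$B_tilde,
                                    m$initial_states[, d],
                                    impulse_inputs(diets$inputs[, d], T_), T_)
    }
  }
  structure(list(trajectories = arr, S = S, provenance = prov),
            class = "state_trajectory_set")
}

#' Pairwise cosine similarity of individual state trajectories
#'
#' For one latent state and one diet, computes the I x I matrix of cosine
#' similarities between individuals' T-point state trajectories.  The
#' diagonal is 1 by definition.
#'
#' @param ts a [extract_state_trajectories()] result.
#' @param state latent state index.
#' @param diet diet index or id.
#' @return An object of class `similarity_matrix` (I x I, symmetric, entries
#'   in \[-1, 1\]).
#' @export
cosine_similarity_matrix <- function(ts, state, diet) {
  stopifnot(inherits(ts, "state_trajectory_set"))
  arr <- ts$trajectories
  if (is.character(diet)) diet <- match(diet, dimnames(arr)[[4]])
  tr <- arr[state, , , diet]                    # T x I
  nrm <- sqrt(colSums(tr^2))
  zero <- which(nrm < 1e-12)
  if (length(zero)) {
    ind_id <- dimnames(arr)[[3]][zero[1]] %||% as.character(zero[1])
    diet_id <- dimnames(arr)[[4]][diet] %||% as.character(diet)
    stopf("zero-norm trajectory for (individual=%s, state=%d, diet=%s)",
          ind_id, state, diet_id)
  }
  cs <- crossprod(tr) / tcrossprod(nrm)
  cs <- (cs + t(cs)) / 2
  diag(cs) <- 1
  structure(cs, class = c("similarity_matrix", class(cs)),
            state_index = state, diet_id = dimnames(arr)[[4]][diet])
}

#' Agglomerative clustering of a similarity matrix
#'
#' Complete-linkage hierarchical clustering on the distance `1 - similarity`,
#' cut at `k` clusters.  Deterministic for a fixed input.
#'
#' @param sim an I x I similarity matrix.
#' @param k number of clusters, `2 <= k <= I`.
#' @return Integer cluster labels of length I.
#' @export
cluster_similarity <- function(sim, k) {
  I <- nrow(sim)
  if (k < 2 || k > I) stopf("`k` must be between 2 and I = %d", I)
  hc <- stats::hclust(stats::as.dist(1 - unclass(sim)), method = "complete")
  stats::cutree(hc, k = k)
}

#' Model order from the scree-plot inflection point
#'
#' Operationalizes the visual knee criterion: the spectrum is normalized by
#' its largest value and the retained dimension S is the index at which the
#' discrete second difference `s[k] - 2 s[k+1] + s[k+2]` is maximal.  When no
#' clear knee exists (maximal second difference below 0.05 on the normalized
#' spectrum) a "weak inflection" warning is raised; the raw spectrum is
#' attached so users can override.
#'
#' @param singular_values non-increasing spectrum, length >= 3.
#' @return Integer S with attribute `second_differences`.
#' @export
scree_inflection <- function(singular_values) {
  s <- as.numeric(singular_values)
  n <- length(s)
  if (n < 3L) stopf("need at least 3 singular values")
  if (is.unsorted(rev(s), strictly = FALSE))
    stopf("singular values must be non-increasing")
  s <- s / s[1]
  d2 <- s[seq_len(n - 2)] - 2 * s[seq_len(n - 2) + 1] + s[seq_len(n - 2) + 2]
  S <- which.max(d2)
  if (max(d2) < 0.05)
    warning("weak inflection: no clear knee in the spectrum", call. = FALSE)
  structure(as.integer(S), second_differences = d2)
}

#' Dominant dynamical classes of metabolite profiles
#'
#' Averages the tensor over individuals and diets to one M x T profile per
#' metabolite, computes the covariance structure across metabolite
#' time-profiles, and groups metabolites by complete-linkage ("farthest
#' distance") agglomerative clustering with one minus the sample correlation
#' as distance.  The per-group mean trajectories are the dominant dynamical
#' profiles that latent states can be compared against.
#'
#' @param x a preprocessed [response_tensor()].
#' @param S number of dynamical classes.
#' @return List with `labels` (per metabolite), `mean_profiles` (S x T),
#'   `mean_data` (M x T averaged tensor) and `covariance` (M x M).
#' @export
dynamical_class_profiles <- function(x, S) {
  stopifnot(inherits(x, "response_tensor"))
  Xbar <- apply(x$values, c(1, 2), mean)          # M x T
  sds <- apply(Xbar, 1, stats::sd)
  if (any(sds <= .Machine$double.eps))
    stopf("constant mean profile(s): %s",
          paste(x$metabolite_ids[sds <= .Machine$double.eps], collapse = ", "))
  C <- stats::cov(t(Xbar))
  if (S == 1L) {
    labels <- stats::setNames(rep(1L, nrow(Xbar)), x$metabolite_ids)
  } else {
    d <- stats::as.dist(1 - stats::cor(t(Xbar)))
    labels <- stats::cutree(stats::hclust(d, method = "complete"), k = S)
    names(labels) <- x$metabolite_ids
  }
  profs <- t(vapply(seq_len(S), function(g)
    colMeans(Xbar[labels == g, , drop = FALSE]), numeric(ncol(Xbar))))
  list(labels = labels, mean_profiles = profs, mean_data = Xbar,
       covariance = C)
}

#' Pearson correlation between two trajectories
#'
#' @param a,b numeric vectors over the same time points; both must be
#'   non-constant.
#' @return Correlation coefficient.
#' @export
profile_correlation <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("constant trajectory: correlation undefined")
  stats::cor(as.numeric(a), as.numeric(b))
}

# ---- CP decomposition (CANDECOMP/PARAFAC) ----------------------------------

# Khatri-Rao (column-wise Kronecker) of a list of matrices; the FIRST matrix
# in the list varies fastest in the result, matching the unfolding
# convention used below.
khatri_rao <- function(mats) {
  Reduce(function(acc, m) {
    # rows of `acc` vary fastest
    out <- matrix(0, nrow(acc) * nrow(m), ncol(acc))
    for (j in seq_len(ncol(acc)))
      out[, j] <- as.vector(outer(acc[, j], m[, j]))
    out
  }, mats)
}

unfold <- function(arr, mode) {
  dm <- dim(arr)
  perm <- c(mode, setdiff(seq_along(dm), mode))
  m <- aperm(arr, perm)
  dim(m) <- c(dm[mode], prod(dm[-mode]))
  m
}

#' Unconstrained CP decomposition of a four-way tensor by ALS
#'
#' Fits `X = sum_f r_f (x) q_f (x) p_f (x) h_f` by alternating least squares,
#' taking the best of `n_starts` random initializations.  Factor modes follow
#' the data layout: `r` metabolite loadings (M x F), `q` time loadings
#' (T x F), `p` individual scores (I x F), `h` diet loadings (D x F); the
#' component magnitudes are folded into `r` and the remaining modes have
#' unit-norm columns, with components ordered by decreasing magnitude.
#'
#' @param x a [response_tensor()] or four-way array.
#' @param n_components number of components F.
#' @param n_starts random restarts (default 5).
#' @param max_iter ALS sweep budget per start (default 500).
#' @param tol relative change in the residual norm declaring convergence
#'   (default 1e-6, the conventional ALS stopping tolerance).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @param scale_metabolites divide each metabolite slice by its global
#'   standard deviation before fitting (the conventional CP preprocessing for
#'   this data; default FALSE so callers control preprocessing).
#' @return An object of class `cp_model`: `factors` (list r, q, p, h),
#'   `explained_variance`, `objective_trace` (per-sweep residual norm of the
#'   best start), `converged`, `degenerate` (two-factor degeneracy flag).
#' @export
cp_als <- function(x, n_components, n_starts = 5L, max_iter = 500L,
                   tol = 1e-6, seed = 1L, scale_metabolites = FALSE) {
  arr <- if (inherits(x, "response_tensor")) x$values else x
  if (length(dim(arr)) != 4L) stopf("need a four-way tensor")
  if (n_components < 1L) stopf("`n_components` must be >= 1")
  if (scale_metabolites) {
    sds <- apply(arr, 1, stats::sd)
    if (any(sds <= .Machine$double.eps)) stopf("constant metabolite slice")
    arr <- arr / sds
  }
  dm <- dim(arr)
  unf <- lapply(1:4, function(k) unfold(arr, k))
  norm_x2 <- sum(arr^2)
  F_ <- as.integer(n_components)
  seeds <- derive_seeds(seed, n_starts)
  best <- NULL
  for (st in seq_len(n_starts)) {
    fac <- with_seed(seeds[st], lapply(dm, function(n)
      matrix(stats::rnorm(n * F_), n, F_)))
    trace <- numeric(0)
    err_prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (k in 1:4) {
        others <- setdiff(1:4, k)
        kr <- khatri_rao(fac[others])
        gram <- Reduce(`*`, lapply(fac[others], crossprod))
        Vk <- unf[[k]] %*% kr
        fac[[k]] <- t(solve(gram + diag(1e-12, F_), t(Vk)))
      }
      # residual via the last-updated mode (k = 4)
      err2 <- norm_x2 - 2 * sum(fac[[4]] * Vk) +
        sum(crossprod(fac[[4]]) * gram)
      err <- sqrt(max(err2, 0))
      trace <- c(trace, err)
      # the shortcut residual cancels catastrophically near an exact fit
      # (its noise floor is sqrt(eps) * ||X||), so a relative residual of
      # 1e-7 is numerically exact and stops the sweep outright
      if (err <= 1e-7 * sqrt(norm_x2) ||
          (is.finite(err_prev) &&
           abs(err_prev - err) <= tol * max(err_prev, 1e-300))) {
        converged <- TRUE
        break
      }
      err_prev <- err
    }
    if (is.null(best) || err < best$err)
      best <- list(fac = fac, err = err, trace = trace, converged = converged)
  }
  fac <- best$fac
  # fold magnitudes into mode 1, unit-normalize modes 2..4
  for (k in 2:4) {
    nrm <- sqrt(colSums(fac[[k]]^2))
    nrm[nrm == 0] <- 1
    fac[[k]] <- sweep(fac[[k]], 2, nrm, "/")
    fac[[1]] <- sweep(fac[[1]], 2, nrm, "*")
  }
  ord <- order(colSums(fac[[1]]^2), decreasing = TRUE)
  fac <- lapply(fac, function(m) m[, ord, drop = FALSE])
  model <- structure(
    list(factors = list(r = fac[[1]], q = fac[[2]], p = fac[[3]],
                        h = fac[[4]]),
         n_components = F_,
         explained_variance = 1 - best$err^2 / norm_x2,
         objective_trace = best$trace, converged = best$converged,
         dims = dm, seed = seed),
    class = "cp_model")
  model$degenerate <- check_two_factor_degeneracy(model)
  if (!best$converged)
    warning("CP-ALS did not converge within max_iter; best iterate returned",
            call. = FALSE)
  model
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf("<cp_model> F = %d components, explained variance = %.4f%s\n",
              x$n_components, x$explained_variance,
              if (x$degenerate) " [two-factor degenerate]" else ""))
  invisible(x)
}

#' Two-factor degeneracy diagnostic for a CP model
#'
#' Flags the standard CP failure mode in which two components grow large and
#' nearly cancel: the triple cosine (product of per-mode factor congruences)
#' of some component pair approaches -1.
#'
#' @param model a [cp_als()] result.
#' @param threshold flag when any pair's triple cosine is below `-threshold`
#'   (default 0.85).
#' @return Logical flag with attribute `min_triple_cosine`.
#' @export
check_two_factor_degeneracy <- function(model, threshold = 0.85) {
  F_ <- model$n_components
  if (F_ < 2L)
    return(structure(FALSE, min_triple_cosine = NA_real_))
  normed <- lapply(model$factors, function(m) {
    nrm <- sqrt(colSums(m^2))
    nrm[nrm == 0] <- 1
    sweep(m, 2, nrm, "/")
  })
  tc <- Reduce(`*`, lapply(normed, crossprod))
  mn <- min(tc[upper.tri(tc)])
  structure(mn < -threshold, min_triple_cosine = mn)
}

#' k-means clustering of CP individual scores
#'
#' @param model a [cp_als()] result.
#' @param k number of clusters, `k <= I`.
#' @param seed RNG seed (k-means uses 50 restarts).
#' @return Integer cluster labels (length I).
#' @export
cluster_cp_scores <- function(model, k, seed = 1L) {
  scores <- model$factors$p
  if (k > nrow(scores)) stopf("`k` exceeds the number of individuals")
  if (k == 1L) return(rep(1L, nrow(scores)))
  if (k == nrow(scores)) return(seq_len(nrow(scores)))  # singletons
  km <- with_seed(seed, stats::kmeans(scores, centers = k, nstart = 50L))
  km$cluster
}

#' Adjusted Rand Index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions (up to relabelling).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Best-matching overlap between two clusterings
#'
#' Maximum fraction of agreeing assignments over all permutations of the
#' label names (optimal matching, so raw label identity does not matter),
#' reported as a percentage with the Adjusted Rand Index attached.
#'
#' @param labels_a,labels_b label vectors of equal length (at most 8 distinct
#'   labels each).
#' @return Percentage (0-100) with attribute `ari`.
#' @export
cluster_overlap <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors differ in length")
  ua <- unique(labels_a); ub <- unique(labels_b)
  if (max(length(ua), length(ub)) > 8L)
    stopf("optimal matching is supported for up to 8 clusters")
  tab <- table(factor(labels_a, ua), factor(labels_b, ub))
  k <- max(nrow(tab), ncol(tab))
  m <- matrix(0, k, k)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- all_permutations(k)
  agree <- max(vapply(perms, function(p) sum(m[cbind(seq_len(k), p)]),
                      numeric(1)))
  structure(100 * agree / length(labels_a),
            ari = adjusted_rand_index(labels_a, labels_b))
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[idx]] <- append(p, k, after = pos)
      idx <- idx + 1L
    }
  }
  out
}

#' One-way ANOVA association of clusters with clinical measures
#'
#' For each clinical measure, tests whether the cluster means differ by
#' one-way ANOVA.  Measures with fewer than two non-missing values in some
#' cluster are skipped with a warning.  No multiplicity correction is applied
#' by default; `adjust = TRUE` adds Benjamini-Hochberg adjusted p-values.
#'
#' @param labels cluster labels (length I).
#' @param clinical a [clinical_table()] with I rows.
#' @param adjust add a BH-adjusted p-value column.
#' @return Data frame with columns `measure`, `F`, `p` (and `p_adj`).
#' @export
anova_association <- function(labels, clinical, adjust = FALSE) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (length(labels) != nrow(clinical$measures))
    stopf("labels length %d does not match %d individuals",
          length(labels), nrow(clinical$measures))
  rows <- list()
  for (j in seq_len(ncol(clinical$measures))) {
    v <- clinical$measures[, j]
    ok <- !is.na(v)
    g <- factor(labels[ok])
    if (nlevels(g) < 2L || any(table(g) < 2L)) {
      warning(sprintf("measure %s skipped: a cluster has fewer than 2 values",
                      clinical$measure_names[j]), call. = FALSE)
      next
    }
    vv <- v[ok]
    grand <- mean(vv)
    ss_between <- sum(tapply(vv, g, length) * (tapply(vv, g, mean) - grand)^2)
    if (ss_between <= .Machine$double.eps * sum(vv^2)) {
      Fstat <- 0; p <- 1
    } else {
      fit <- stats::anova(stats::lm(vv ~ g))
      Fstat <- fit$`F value`[1]
      p <- fit$`Pr(>F)`[1]
    }
    rows[[length(rows) + 1L]] <-
      data.frame(measure = clinical$measure_names[j], F = Fstat, p = p)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(measure = character(), F = numeric(), p = numeric())
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
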