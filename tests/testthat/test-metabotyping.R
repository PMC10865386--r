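shared_fit_fixture <- function(seed = 1, I = 6, S = 3, M = 15, D = 3,
                               noise_sd = 0) {
  spec <- population_spec(M = M, I = I, D = D, S_true = S, l = 2,
                          noise_sd = noise_sd, baseline_sd = 0,
                          baseline_mean = 0, seed = seed)
  gt <- sample_population(spec)
  diets <- sample_diet_inputs(D, spec)
  x <- subtract_baseline(simulate_population_tensor(gt, diets)$tensor)
  basis <- compute_shared_basis(x, S)
  models <- fit_shared_latent(x, diets, basis)
  list(x = x, diets = diets, basis = basis, models = models, gt = gt)
}

test_that("rolled state trajectories match the projected data (noiseless)", {
  f <- shared_fit_fixture(seed = 2)
  ts <- extract_state_trajectories(f$models, f$diets, T_ = 8)
  expect_identical(dim(ts$trajectories), c(3L, 8L, 6L, 3L))
  for (i in c(1, 4)) for (d in 1:3) {
    proj <- crossprod(f$basis$U_tot, f$x$values[, , i, d])
    expect_equal(ts$trajectories[, , i, d], proj, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("cosine similarity matches the inner-product formula and its bounds", {
  # hand-built trajectory set: 3 individuals, 1 state, 1 diet
  arr <- array(0, c(1, 2, 3, 1))
  arr[1, , 1, 1] <- c(1, 0)
  arr[1, , 2, 1] <- c(1, 1)
  arr[1, , 3, 1] <- -c(1, 0)
  ts <- structure(list(trajectories = arr, S = 1, provenance = NULL),
                  class = "state_trajectory_set")
  cs <- cosine_similarity_matrix(ts, 1, 1)
  expect_equal(cs[1, 2], 0.70710678, tolerance = 1e-8)
  expect_equal(cs[1, 3], -1)
  expect_equal(diag(cs), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(cs), t(unclass(cs)), ignore_attr = TRUE)

  arr[1, , 3, 1] <- 0
  ts$trajectories <- arr
  expect_error(cosine_similarity_matrix(ts, 1, 1), "zero-norm")

  # property: symmetric, unit diagonal, entries within [-1, 1]
  f <- shared_fit_fixture(seed = 3, noise_sd = 0.05)
  tss <- extract_state_trajectories(f$models, f$diets, T_ = 8)
  for (s in 1:3) for (d in 1:3) {
    m <- cosine_similarity_matrix(tss, s, d)
    expect_true(all(abs(m) <= 1 + 1e-12))
    expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(diag(m), rep(1, 6), ignore_attr = TRUE)
  }
})

test_that("similarity clustering recovers planted blocks and handles bounds", {
  sim <- rbind(c(1, .95, .1, .05), c(.95, 1, .02, .1),
               c(.1, .02, 1, .9), c(.05, .1, .9, 1))
  lab <- cluster_similarity(sim, 2)
  expect_identical(lab[1], lab[2])
  expect_identical(lab[3], lab[4])
  expect_false(lab[1] == lab[3])
  expect_identical(sort(unique(cluster_similarity(sim, 4))), 1:4)
  expect_error(cluster_similarity(sim, 5), "between 2 and")
})

test_that("scree inflection maximizes the second difference", {
  s <- c(10, 8, 6, 4, 0.1, 0.09, 0.08)
  # brute-force oracle over interior points
  d2 <- vapply(2:6, function(k) s[k - 1] - 2 * s[k] + s[k + 1], numeric(1))
  expect_identical(as.integer(scree_inflection(s)), as.integer(which.max(d2)))
  expect_identical(as.integer(scree_inflection(s)), 4L)

  # exact rank: S nonzero values then zeros
  expect_identical(as.integer(scree_inflection(c(3, 2, 1, 0, 0, 0))), 3L)

  # geometric decay has no knee: warns but still returns the argmax
  geo <- 0.8^(0:9)
  expect_warning(S_geo <- scree_inflection(geo), "weak inflection")
  d2g <- vapply(2:9, function(k) geo[k - 1] - 2 * geo[k] + geo[k + 1],
                numeric(1)) / geo[1]
  expect_identical(as.integer(S_geo), as.integer(which.max(d2g)))
  expect_error(scree_inflection(c(2, 1)), "at least 3")
  expect_error(scree_inflection(c(1, 2, 3)), "non-increasing")
})

test_that("dynamical classes recover template profiles", {
  T_ <- 8
  t1 <- sin(seq(0, pi, length.out = T_))          # early peak
  t2 <- seq(0, 1, length.out = T_)^2              # late rise
  arr <- withr::with_seed(9, {
    a <- array(0, c(12, T_, 3, 2))
    for (m in 1:12) {
      base <- if (m <= 6) t1 else t2
      for (i in 1:3) for (d in 1:2)
        a[m, , i, d] <- base * runif(1, 0.5, 2) + rnorm(T_, sd = 1e-3)
    }
    a
  })
  x <- response_tensor(arr)
  out <- dynamical_class_profiles(x, 2)
  expect_identical(unname(out$labels[1:6]), rep(out$labels[[1]], 6))
  expect_identical(unname(out$labels[7:12]), rep(out$labels[[7]], 6))
  expect_false(out$labels[[1]] == out$labels[[7]])
  # group mean profiles correlate with their generating templates
  g1 <- out$labels[[1]]
  expect_gt(cor(out$mean_profiles[g1, ], t1), 0.99)
  expect_gt(cor(out$mean_profiles[3 - g1, ], t2), 0.99)

  one <- dynamical_class_profiles(x, 1)
  expect_equal(one$mean_profiles[1, ], colMeans(out$mean_data),
               ignore_attr = TRUE)
})

test_that("profile correlation is Pearson over time points", {
  expect_equal(profile_correlation(1:5, 1:5), 1)
  expect_equal(profile_correlation(1:5, -2 * (1:5) + 3), -1)
  expect_equal(profile_correlation(c(1, 2, 3), c(1, 2, 4)), 0.98198,
               tolerance = 1e-5)
  expect_error(profile_correlation(c(1, 1, 1), 1:3), "constant")
})

test_that("CP-ALS recovers planted low-rank tensors", {
  p1 <- planted_cp_tensor(c(6, 5, 4, 3), 1, seed = 11)
  m1 <- cp_als(p1$tensor, 1, n_starts = 2, seed = 1)
  expect_gt(m1$explained_variance, 0.99999)
  expect_gt(factor_congruence(unname(m1$factors), p1$factors), 0.9999)

  p2 <- planted_cp_tensor(c(7, 6, 5, 4), 2, seed = 12)
  m2 <- cp_als(p2$tensor, 2, n_starts = 4, seed = 2)
  expect_gt(m2$explained_variance, 0.9999)
  expect_gt(factor_congruence(unname(m2$factors), p2$factors), 0.99)

  # ALS objective is non-increasing across sweeps
  noisy <- p2$tensor + withr::with_seed(13, array(rnorm(length(p2$tensor),
                                                        sd = 0.1),
                                                  dim(p2$tensor)))
  m3 <- cp_als(noisy, 2, n_starts = 3, seed = 3)
  expect_true(all(diff(m3$objective_trace) <=
                    1e-8 * (1 + m3$objective_trace[1])))
  expect_true(m3$explained_variance >= 0 && m3$explained_variance <= 1)
})

test_that("two-factor degeneracy fires on near-cancelling pairs only", {
  mk <- function(cos1) {
    # mode-1 factors with prescribed cosine, other modes identical columns
    u <- c(1, 0, 0); v <- c(cos1, sqrt(1 - cos1^2), 0)
    structure(list(factors = list(r = cbind(u, v) * 5,
                                  q = cbind(c(1, 1), c(1, 1)),
                                  p = cbind(c(1, 2), c(1, 2)),
                                  h = cbind(c(2, 1), c(2, 1))),
                   n_components = 2L), class = "cp_model")
  }
  deg <- check_two_factor_degeneracy(mk(-0.95))
  expect_true(deg)
  expect_equal(attr(deg, "min_triple_cosine"), -0.95, tolerance = 1e-12)
  expect_false(check_two_factor_degeneracy(mk(-0.95), threshold = 1.0))
  expect_false(check_two_factor_degeneracy(mk(0)))

  p2 <- planted_cp_tensor(c(7, 6, 5, 4), 2, seed = 14)
  expect_false(cp_als(p2$tensor, 2, n_starts = 3, seed = 4)$degenerate)
  expect_false(check_two_factor_degeneracy(
    structure(list(n_components = 1L), class = "cp_model")))
})

test_that("k-means on CP scores separates well-separated blobs", {
  scores <- withr::with_seed(15, rbind(matrix(rnorm(20, 0, 0.2), 10),
                                       matrix(rnorm(20, 5, 0.2), 10)))
  model <- structure(list(factors = list(p = scores), n_components = 2L),
                     class = "cp_model")
  lab <- cluster_cp_scores(model, 2, seed = 1)
  expect_equal(adjusted_rand_index(lab, rep(1:2, each = 10)), 1)
  expect_identical(cluster_cp_scores(model, 1), rep(1L, 20))
  expect_error(cluster_cp_scores(model, 21), "exceeds")
})

test_that("cluster overlap uses optimal label matching", {
  a <- rep(1:2, c(9, 8))
  expect_equal(as.numeric(cluster_overlap(a, a)), 100)
  # permuted label names still count as full agreement
  expect_equal(as.numeric(cluster_overlap(a, 3 - a)), 100)
  b <- a; b[17] <- 1
  expect_equal(as.numeric(cluster_overlap(a, b)), 100 * 16 / 17,
               tolerance = 1e-10)
  # label-permutation invariance and agreement with the ARI cross-check
  expect_equal(attr(cluster_overlap(a, b), "ari"),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  expect_error(cluster_overlap(a, a[-1]), "length")
})

test_that("in-package ARI agrees with the mclust reference", {
  for (seed in 1:5) {
    lab <- withr::with_seed(seed, list(a = sample(1:3, 30, TRUE),
                                       b = sample(1:4, 30, TRUE)))
    expect_equal(adjusted_rand_index(lab$a, lab$b),
                 mclust::adjustedRandIndex(lab$a, lab$b), tolerance = 1e-12)
  }
})

test_that("ANOVA association reports F and p per measure", {
  # identical values within and between groups: F = 0, p = 1 by convention
  cl <- clinical_table(matrix(5, 8, 1), "flat")
  out <- anova_association(rep(1:2, each = 4), cl)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)

  # strongly separated groups: closed-form one-way F oracle
  v <- withr::with_seed(20, c(rnorm(8, 0, 1), rnorm(8, 10, 1)))
  g <- rep(1:2, each = 8)
  cl2 <- clinical_table(matrix(v, 16, 1), "sep")
  out2 <- anova_association(g, cl2)
  gm <- mean(v)
  ssb <- sum(8 * (tapply(v, g, mean) - gm)^2)
  ssw <- sum((v - rep(tapply(v, g, mean), each = 8))^2)
  F_oracle <- (ssb / 1) / (ssw / 14)
  expect_equal(out2$F, F_oracle, tolerance = 1e-10)
  expect_lt(out2$p, 1e-6)

  # measure missing in one cluster is skipped with a warning
  m <- cbind(ok = v, gone = c(v[1:8], rep(NA, 8)))
  expect_warning(out3 <- anova_association(g, clinical_table(m)),
                 "skipped")
  expect_identical(out3$measure, "ok")
})

test_that("clustering pipelines are label-permutation equivariant", {
  f <- shared_fit_fixture(seed = 5, I = 8, noise_sd = 0.02)
  ts <- extract_state_trajectories(f$models, f$diets, T_ = 8)
  cs <- cosine_similarity_matrix(ts, 2, 1)
  lab <- cluster_similarity(cs, 2)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  cs_p <- unclass(cs)[perm, perm]
  lab_p <- cluster_similarity(cs_p, 2)
  expect_equal(as.numeric(cluster_overlap(lab_p, lab[perm])), 100)
})
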