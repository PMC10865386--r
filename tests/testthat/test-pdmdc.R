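test_that("diet-concatenated snapshots have block structure and impulse columns", {
  responses <- withr::with_seed(1, lapply(1:3, function(d)
    list(series = matrix(rnorm(79 * 8), 79, 8), z1 = rnorm(3))))
  ms <- concat_response_snapshots(responses)
  expect_identical(dim(ms$X), c(79L, 21L))
  expect_identical(dim(ms$Omega), c(82L, 21L))
  expect_identical(ms$impulse_columns, c(1L, 8L, 15L))
  # impulse columns carry the diet vectors, all other input columns are zero
  expect_equal(ms$Z[, ms$impulse_columns],
               vapply(responses, `[[`, numeric(3), "z1"))
  expect_equal(sum(abs(ms$Z[, -ms$impulse_columns])), 0)

  one <- concat_response_snapshots(responses[1])
  single <- build_snapshots(responses[[1]]$series, responses[[1]]$z1)
  expect_equal(one$Omega, single$Omega)
  expect_error(concat_response_snapshots(list()), "at least one")
})

test_that("fitted operators are invariant to diet block order", {
  sys <- rand_lds(4, 2, seed = 3)
  diets <- withr::with_seed(4, matrix(runif(2 * 3, 1, 5), 2, 3))
  obs <- lds_observations(sys, diets, T_ = 8)
  fit1 <- fit_dmdc(concat_response_snapshots(obs), 6)
  fit2 <- fit_dmdc(concat_response_snapshots(obs[c(3, 1, 2)]), 6)
  expect_equal(fit1$A_hat, fit2$A_hat, tolerance = 1e-9)
  expect_equal(fit1$B_hat, fit2$B_hat, tolerance = 1e-9)
})

test_that("per-individual fit recovers a known system from three impulses", {
  M <- 4; l <- 2
  sys <- rand_lds(M, l, seed = 7)
  diets <- withr::with_seed(8, matrix(runif(l * 3, 1, 6), l, 3))
  obs <- lds_observations(sys, diets, T_ = 8)   # D(T-1) = 21 >= M + l
  ms <- concat_response_snapshots(obs)
  V <- sum(svd(ms$Omega)$d > 1e-9)
  im <- fit_individual(ms, V, S = M, individual_id = "i1")
  # recovery holds after lifting the latent operators back to full space
  A_lift <- im$U_map %*% im$A_tilde %*% t(im$U_map)
  B_lift <- im$U_map %*% im$B_tilde
  expect_lt(sum(abs(A_lift - sys$A)) + sum(abs(B_lift - sys$B)), 1e-7)
  # latent simulation lifts to the full simulation at S = M
  for (d in 1:3) {
    lat <- simulate_lds(im$A_tilde, im$B_tilde, im$initial_states[, d],
                        impulse_inputs(diets[, d], 8), 8)
    expect_equal(im$U_map %*% lat, obs[[d]]$series, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("duplicate diets add no rank", {
  sys <- rand_lds(3, 1, seed = 12)
  diets <- withr::with_seed(13, matrix(runif(3, 1, 4), 1, 3))
  diets[, 3] <- diets[, 1]
  obs <- lds_observations(sys, diets, T_ = 6)
  ms_dup <- concat_response_snapshots(obs)
  ms_ded <- concat_response_snapshots(obs[1:2])
  rk <- function(m) sum(svd(m)$d > 1e-10)
  expect_identical(rk(ms_dup$Omega), rk(ms_ded$Omega))
})

test_that("shared basis has the documented shape and captures planted subspaces", {
  pop <- synthetic_preset("measured-like", seed = 2, noise_sd = 0)
  x <- subtract_baseline(pop$tensor)
  expect_identical(dim(pdmdc:::flatten_tensor(x)), c(79L, 408L))  # T*D*I

  b <- compute_shared_basis(x, 5)
  expect_equal(crossprod(b$U_tot), diag(5), tolerance = 1e-12,
               ignore_attr = TRUE)

  # tensor generated from a rank-3 latent signal: 3 components carry
  # essentially all Frobenius mass
  U <- qr.Q(qr(withr::with_seed(5, matrix(rnorm(20 * 3), 20, 3))))
  lat <- withr::with_seed(6, matrix(rnorm(3 * 8 * 4 * 2), 3))
  arr <- array(U %*% lat, c(20, 8, 4, 2))
  b3 <- compute_shared_basis(response_tensor(arr), 3)
  mass <- sum(b3$singular_values[1:3]^2) / sum(b3$singular_values^2)
  expect_gt(mass, 0.99999)
  expect_error(compute_shared_basis(response_tensor(arr), 10), "rank")
})

test_that("shared-latent fits recover individual latent dynamics (noiseless)", {
  spec <- population_spec(M = 15, I = 4, D = 4, S_true = 3, l = 2,
                          noise_sd = 0, baseline_sd = 0, baseline_mean = 0,
                          seed = 9)
  gt <- sample_population(spec)
  diets <- sample_diet_inputs(4, spec)
  sim <- simulate_population_tensor(gt, diets)
  x <- subtract_baseline(sim$tensor)
  basis <- compute_shared_basis(x, 3)
  models <- fit_shared_latent(x, diets, basis)
  # recovered latent operator, rotated back through the shared basis, matches
  # the generating dynamics individual by individual
  R <- crossprod(basis$U_tot, gt$U_true)     # S x S rotation
  for (i in seq_along(models)) {
    A_back <- solve(R) %*% models[[i]]$A_tilde %*% R
    expect_equal(A_back, gt$A[[i]], tolerance = 1e-6, ignore_attr = TRUE)
  }
  # identical individuals yield identical latent trajectories
  ts <- extract_state_trajectories(models, diets, T_ = 8)
  expect_identical(dim(ts$trajectories), c(3L, 8L, 4L, 4L))
})

test_that("pooled fit reduces to fit_dmdc and has the documented column count", {
  sys <- rand_lds(3, 1, seed = 20)
  obs <- lds_observations(sys, matrix(c(2, 3, 4), 1), T_ = 8)
  pooled1 <- fit_pooled(obs[1], V = 4)
  direct <- fit_dmdc(build_snapshots(obs[[1]]$series, obs[[1]]$z1), V = 4)
  expect_equal(pooled1$A_hat, direct$A_hat)

  # 51 observations of 8 time points give a 357-column snapshot stack
  obs51 <- rep(obs, length.out = 51)
  ms <- concat_response_snapshots(obs51)
  expect_identical(ms$N, 357L)
})

test_that("prediction is exact for memorized diets and linear in the input", {
  M <- 5; l <- 2
  sys <- rand_lds(M, l, seed = 30)
  diets <- withr::with_seed(31, matrix(runif(l * 6, 1, 5), l, 6))
  obs <- lds_observations(sys, diets, T_ = 8)
  model <- fit_pooled(obs, V = sum(svd(concat_response_snapshots(obs)$Omega)$d > 1e-9))
  # memorization: a training diet is reproduced from baseline + impulse alone
  pred <- predict_response(model, diets[, 2], 8)
  expect_equal(pred, obs[[2]]$series, tolerance = 1e-8, ignore_attr = TRUE)
  # zero diet, zero baseline-subtracted state: identically zero response
  expect_equal(predict_response(model, c(0, 0), 8), matrix(0, M, 8),
               ignore_attr = TRUE)
  # superposition: prediction is exactly linear in the diet vector
  u <- c(1, 2); v <- c(3, -1); a <- 0.7; b <- -1.3
  expect_equal(predict_response(model, a * u + b * v, 8),
               a * predict_response(model, u, 8) +
                 b * predict_response(model, v, 8), tolerance = 1e-9)
})

test_that("held-out diets are predicted from spanning training diets", {
  M <- 6; l <- 2
  sys <- rand_lds(M, l, seed = 40)
  diets <- withr::with_seed(41, matrix(runif(l * 11, 1, 6), l, 11))
  train <- lds_observations(sys, diets[, 1:10], T_ = 8)
  test <- lds_observations(sys, diets[, 11, drop = FALSE], T_ = 8)[[1]]
  V <- sum(svd(concat_response_snapshots(train)$Omega)$d > 1e-9)
  model <- fit_pooled(train, V)
  pred <- predict_response(model, test$z1, 8)
  expect_gt(r_squared(pred, test$series), 0.99)
})

test_that("the pdmdc() front-end ties the pieces together", {
  pop <- synthetic_preset("measured-like", seed = 3, M = 20L)
  x <- subtract_baseline(pop$tensor)
  fit <- pdmdc(x, pop$diets, method = "pooled")
  expect_s3_class(fit, "pdmdc")
  expect_output(print(fit), "pooled")
  cf <- coef(fit)
  expect_identical(dim(cf$A), c(20L, 20L))
  expect_identical(dim(cf$B), c(20L, 3L))
  pred <- predict(fit, diet = pop$diets$inputs[, 2], horizon = 8)
  expect_identical(dim(pred), c(20L, 8L))
  expect_identical(dim(residuals(fit)), c(20L, 51L * 7L))
  expect_length(simulate(fit), 51L)

  shared <- pdmdc(x, pop$diets, method = "shared", latent_dim = 4)
  expect_identical(dim(simulate(shared)$trajectories), c(4L, 8L, 17L, 3L))
  expect_error(predict(shared, diet = pop$diets$inputs[, 1]), "pooled")
})

test_that("latent trajectories are unchanged under individual permutation", {
  pop <- synthetic_preset("measured-like", seed = 4, M = 12L, I = 6L)
  x <- subtract_baseline(pop$tensor)
  basis <- compute_shared_basis(x, 3)
  models <- fit_shared_latent(x, pop$diets, basis)
  ts <- extract_state_trajectories(models, pop$diets, T_ = 8)
  perm <- c(4, 2, 6, 1, 3, 5)
  xp <- response_tensor(x$values[, , perm, ], x$metabolite_ids,
                        x$time_points, x$individual_ids[perm], x$diet_ids,
                        x$preprocessing_log)
  basis_p <- compute_shared_basis(xp, 3)
  expect_equal(basis_p$U_tot, basis$U_tot, tolerance = 1e-9)
  models_p <- fit_shared_latent(xp, pop$diets, basis_p)
  ts_p <- extract_state_trajectories(models_p, pop$diets, T_ = 8)
  expect_equal(ts_p$trajectories, ts$trajectories[, , perm, ],
               tolerance = 1e-8, ignore_attr = TRUE)
})
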