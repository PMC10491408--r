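test_that("model log-evidence matches its closed form and scaling laws", {
  ssm <- random_scalar_ssm(3)
  set.seed(3); y <- rnorm(6)
  R <- matrix(0.4)
  sm <- rts_smooth(kalman_filter(ssm, y, R))
  g <- model_log_evidence(ssm, sm, y, R)
  manual <- vapply(1:6, function(t) {
    r <- y[t] - ssm$G[1] * sm$x_sm[1, t + 1]
    -0.5 * (r^2 + ssm$G[1]^2 * sm$P_sm[1, 1, t + 1]) / R[1]
  }, numeric(1))
  expect_equal(g, manual, tolerance = 1e-12)
  # doubling R halves g exactly
  sm2 <- sm
  expect_equal(model_log_evidence(ssm, sm, y, 2 * R), g / 2,
               tolerance = 1e-12)
})

test_that("model log-evidence equals the Monte-Carlo expectation", {
  ssm <- gaussian_ssm(mu = 0, Q0 = matrix(1), F = matrix(0.5), Q = matrix(1),
                      G = matrix(1.2))
  R <- matrix(0.5)
  set.seed(91); y <- rnorm(3)
  sm <- rts_smooth(kalman_filter(ssm, y, R))
  g <- model_log_evidence(ssm, sm, y, R)
  t0 <- 2
  set.seed(92)
  draws <- rnorm(1e5, sm$x_sm[1, t0 + 1], sqrt(sm$P_sm[1, 1, t0 + 1]))
  vals <- -0.5 * (y[t0] - ssm$G[1] * draws)^2 / R[1]
  mc_se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(g[t0] - mean(vals)), 3 * mc_se)
})

test_that("zero residual with zero covariance gives zero evidence", {
  ssm <- make_ar1(0.5, 1)
  sm <- rts_smooth(kalman_filter(ssm, c(1, 2), matrix(0.1)))
  sm$x_sm[1, 2:3] <- c(1, 2)
  sm$P_sm[1, 1, 2:3] <- 0
  expect_equal(model_log_evidence(ssm, sm, c(1, 2), matrix(0.1)), c(0, 0))
})

test_that("annealing schedule and scaling follow the decay rule", {
  temps <- annealing_schedule(100, 4)
  expect_equal(temps, c(100, 50.5, 25.75, 13.375))
  expect_true(all(diff(temps) < 0))
  g <- matrix(as.numeric(1:6), 3, 2); h <- matrix(0.5, 3, 2)
  out <- anneal_evidence(g, h, 1)
  expect_identical(out$g, g)
  expect_identical(out$h, h)
  out2 <- anneal_evidence(g, h, 1e6)
  expect_lt(max(abs(out2$g)), 1e-5)
  expect_error(anneal_evidence(g, h, 0.5), "temperature")
})

test_that("interpolated evidence initialization and centering behave", {
  ssm <- make_ar1(0.9, 1)
  model <- switching_model(list(ssm, ssm),
                           markov_chain(c(0.5, 0.5), phi_diag(2, 0.9)),
                           matrix(0.2))
  set.seed(5); y <- rnorm(30)
  g <- init_evidence_interpolated(model, y)
  expect_equal(g[, 1], g[, 2], tolerance = 1e-12)  # identical candidates
  gc <- init_evidence_interpolated(model, y, center = TRUE)
  expect_lt(max(abs(colMeans(gc))), 1e-12)
  # nested oscillator candidates: centering is on by default and the richer
  # model's raw evidence mean is larger on data containing both oscillations
  specs <- list(oscillator_spec(0.98, 2, 100, 3), oscillator_spec(0.98, 12, 100, 3))
  nest <- build_nested_oscillator_models(specs, R = matrix(1))
  sim <- simulate_nested_oscillators(nest, specs, 300, seed = 6)
  graw <- init_evidence_interpolated(nest, sim$y, center = FALSE)
  expect_gt(mean(graw[, 3]), mean(graw[, 1]))
  expect_gt(mean(graw[, 3]), mean(graw[, 2]))
  gdef <- init_evidence_interpolated(nest, sim$y)
  expect_lt(max(abs(colMeans(gdef))), 1e-10)
})

test_that("single-candidate E-step is exact", {
  m1 <- switching_model(list(make_ar1(0.9, 1)), markov_chain(1, matrix(1)),
                        matrix(0.2))
  set.seed(14); y <- rnorm(25)
  est <- fixed_point_estep(m1, y, estep_config("interpolated", max_iter = 4))
  expect_equal(unname(est$h[, 1]), rep(1, 25))
  ll <- kalman_filter(m1$ssms[[1]], y, m1$R)$loglik
  expect_equal(est$free_energy, ll, tolerance = 1e-8)
  sm <- rts_smooth(kalman_filter(m1$ssms[[1]], y, m1$R))
  expect_equal(est$smoothers[[1]]$x_sm, sm$x_sm, tolerance = 1e-12)
})

test_that("free energy lower-bounds the exact switching log-likelihood", {
  model <- ar1_switching_model()
  for (seed in c(2, 9, 33)) {
    sim <- simulate_switching(model, 8, seed = seed)
    exact <- enumerate_switching_loglik(model, sim$y)
    for (mode in c("interpolated", "annealed")) {
      est <- fixed_point_estep(model, sim$y,
                               estep_config(mode, max_iter = 15),
                               anneal = annealing_schedule(100, 6))
      expect_lte(est$free_energy, exact + 1e-8)
    }
  }
})

test_that("fixed-point cycles weakly increase the free energy", {
  model <- ar1_switching_model()
  for (seed in 101:104) {
    sim <- simulate_switching(model, 40, seed = seed)
    est <- fixed_point_estep(model, sim$y,
                             estep_config("interpolated", max_iter = 20))
    expect_true(all(diff(est$free_energy_trace) > -1e-8))
  }
})

test_that("warm starts reproduce the cycle they are given", {
  model <- ar1_switching_model()
  sim <- simulate_switching(model, 30, seed = 55)
  g0 <- init_evidence_interpolated(model, sim$y)
  est_g <- fixed_point_estep(model, sim$y,
                             estep_config("given_g", max_iter = 5),
                             g_init = g0)
  est_i <- fixed_point_estep(model, sim$y,
                             estep_config("interpolated", max_iter = 5))
  expect_equal(est_g$h, est_i$h, tolerance = 1e-12)
  est_h <- fixed_point_estep(model, sim$y,
                             estep_config("given_h", max_iter = 5),
                             h_init = est_i$h)
  expect_true(is.finite(est_h$free_energy))
})

test_that("responsibilities polarize on the AR1 benchmark", {
  model <- ar1_switching_model()
  frac <- vapply(1:10, function(i) {
    sim <- simulate_switching(model, 200, seed = 400 + i)
    est <- fixed_point_estep(model, sim$y,
                             estep_config("interpolated", max_iter = 12))
    mean(est$h < 0.1 | est$h > 0.9)
  }, numeric(1))
  expect_gt(mean(frac), 0.9)
})

test_that("interpolated init alone already segments far better than chance", {
  model <- ar1_switching_model()
  acc <- vapply(1:50, function(i) {
    sim <- simulate_switching(model, 200, seed = 6000 + i)
    g <- init_evidence_interpolated(model, sim$y)
    post <- forward_backward(g, model$chain)
    segmentation_accuracy(post$h, sim$s)
  }, numeric(1))
  expect_gt(mean(acc), 0.6)
})
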