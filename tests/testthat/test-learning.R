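naive_stats <- function(sm, T_) {
  # brute-force per-term summation of the second-moment statistics
  d <- nrow(sm$x_sm)
  A <- B <- C <- matrix(0, d, d)
  for (t in seq_len(T_)) {
    A <- A + sm$P_sm[, , t] + tcrossprod(sm$x_sm[, t])
    B <- B + sm$P_lag[, , t] + tcrossprod(sm$x_sm[, t + 1], sm$x_sm[, t])
    C <- C + sm$P_sm[, , t + 1] + tcrossprod(sm$x_sm[, t + 1])
  }
  list(A = A, B = B, C = C)
}

trivial_markov <- function(T_, M = 1L) {
  structure(list(h = matrix(1 / M, T_, M), p0 = rep(1 / M, M),
                 pairwise = array(1 / M^2, c(M, M, T_))),
            class = "markov_posterior")
}

test_that("sufficient statistics match naive summation", {
  ssm <- random_mv_ssm(61, d = 2, p = 1)
  set.seed(61); y <- rnorm(12)
  sm <- rts_smooth(kalman_filter(ssm, y, matrix(0.3)))
  st <- collect_stats(list(sm), trivial_markov(12), y)
  ns <- naive_stats(sm, 12)
  expect_equal(st$per_model[[1]]$A, ns$A, tolerance = 1e-10)
  expect_equal(st$per_model[[1]]$B, ns$B, tolerance = 1e-10)
  expect_equal(st$per_model[[1]]$C, ns$C, tolerance = 1e-10)
})

test_that("T = 1 statistics reduce to the direct formula", {
  ssm <- random_scalar_ssm(71)
  y <- 0.7
  sm <- rts_smooth(kalman_filter(ssm, y, matrix(0.2)))
  st <- collect_stats(list(sm), trivial_markov(1), y)
  expect_equal(st$per_model[[1]]$A[1, 1],
               sm$P_sm[1, 1, 1] + sm$x_sm[1, 1]^2, tolerance = 1e-12)
  expect_equal(st$per_model[[1]]$C[1, 1],
               sm$P_sm[1, 1, 2] + sm$x_sm[1, 2]^2, tolerance = 1e-12)
})

test_that("single-model M-step reproduces the textbook linear-Gaussian EM", {
  ssm <- random_mv_ssm(81, d = 2, p = 1)
  set.seed(81); y <- rnorm(30)
  R <- matrix(0.4)
  sm <- rts_smooth(kalman_filter(ssm, y, R))
  st <- collect_stats(list(sm), trivial_markov(30), y)
  model <- switching_model(list(ssm), markov_chain(1, matrix(1)), R)
  up <- mstep(model, st, em_config())
  # independent textbook computation from the same statistics
  pm <- st$per_model[[1]]
  F_ref <- pm$B %*% solve(pm$A)
  Q_ref <- (pm$C - pm$B %*% t(F_ref) - F_ref %*% t(pm$B) +
            F_ref %*% pm$A %*% t(F_ref)) / 30
  ym <- matrix(y, ncol = 1)
  x1 <- sm$x_sm[, -1]
  R_ref <- 0
  for (t in 1:30) {
    r <- y[t] - ssm$G %*% x1[, t]
    R_ref <- R_ref + tcrossprod(r) + ssm$G %*% sm$P_sm[, , t + 1] %*% t(ssm$G)
  }
  R_ref <- R_ref / 30
  expect_equal(up$ssms[[1]]$F, F_ref, tolerance = 1e-10)
  expect_equal(up$ssms[[1]]$Q, 0.5 * (Q_ref + t(Q_ref)), tolerance = 1e-10)
  expect_equal(up$R[1, 1], R_ref[1, 1], tolerance = 1e-10)
  expect_equal(up$ssms[[1]]$mu, unname(sm$x_sm[, 1]), tolerance = 1e-12)
})

test_that("the M-step never decreases the expected complete log-likelihood", {
  model <- ar1_switching_model()
  for (seed in c(7, 19)) {
    sim <- simulate_switching(model, 60, seed = seed)
    est <- fixed_point_estep(model, sim$y,
                             estep_config("interpolated", max_iter = 8))
    st <- collect_stats(est$smoothers, est$markov, sim$y)
    before <- expected_cll(model, st)
    after <- expected_cll(mstep(model, st, em_config()), st)
    expect_gte(after, before - 1e-8)
  }
  # also with element-tied F and pooled Q
  bm <- bivariate_coupled_model(tied = TRUE)
  sim <- simulate_bivariate_coupled(60, seed = 23)
  est <- fixed_point_estep(bm, sim$y, estep_config("interpolated", max_iter = 8))
  st <- collect_stats(est$smoothers, est$markov, sim$y)
  expect_gte(expected_cll(mstep(bm, st, em_config()), st),
             expected_cll(bm, st) - 1e-8)
})

test_that("singleton tying groups reproduce the untied updates bitwise", {
  model <- ar1_switching_model()
  sim <- simulate_switching(model, 50, seed = 31)
  est <- fixed_point_estep(model, sim$y,
                           estep_config("interpolated", max_iter = 6))
  st <- collect_stats(est$smoothers, est$markov, sim$y)
  untied <- mstep(model, st, em_config())
  tied_model <- model
  tied_model$tying <- tying_spec(F_ids = list(matrix(1, 1, 1), matrix(2, 1, 1)))
  tied <- mstep(tied_model, st, em_config())
  expect_identical(untied$ssms[[1]]$F, tied$ssms[[1]]$F)
  expect_identical(untied$ssms[[2]]$F, tied$ssms[[2]]$F)
})

test_that("element-tied F shares estimates and keeps fixed entries", {
  bm <- bivariate_coupled_model(tied = TRUE)
  sim <- simulate_bivariate_coupled(120, seed = 41)
  est <- fixed_point_estep(bm, sim$y, estep_config("interpolated", max_iter = 10))
  st <- collect_stats(est$smoothers, est$markov, sim$y)
  up <- mstep(bm, st, em_config())
  F1 <- up$ssms[[1]]$F; F2 <- up$ssms[[2]]$F
  expect_identical(F1[1, 1], F2[1, 1])  # shared diagonal
  expect_identical(F1[2, 2], F2[2, 2])
  expect_identical(F1[2, 1], 0)         # fixed zeros untouched
  expect_identical(F2[1, 2], 0)
  expect_false(isTRUE(all.equal(F1[1, 2], 0)))  # free coupling estimated
  expect_identical(up$ssms[[1]]$Q, up$ssms[[2]]$Q)  # pooled Q
})

test_that("chain updates are properly normalized posteriors", {
  model <- ar1_switching_model()
  sim <- simulate_switching(model, 80, seed = 51)
  est <- fixed_point_estep(model, sim$y,
                           estep_config("interpolated", max_iter = 8))
  st <- collect_stats(est$smoothers, est$markov, sim$y)
  up <- mstep(model, st, em_config())
  expect_equal(sum(up$chain$rho), 1, tolerance = 1e-10)
  expect_equal(colSums(up$chain$phi), c(1, 1), tolerance = 1e-10)
})

test_that("learned self-transition probabilities exceed the true 0.95 on average", {
  phis <- vapply(1:25, function(i) {
    gen <- ar1_switching_model(f = c(0.90, 0.70), q = c(2, 10), r = 0.1)
    sim <- simulate_switching(gen, 200, seed = 7000 + i)
    init <- switchssm:::draw_ar1_learning_init()
    fit <- suppressWarnings(
      vbem(init, sim$y, estep_config("interpolated"), em_config()))
    mean(diag(fit$model$chain$phi))
  }, numeric(1))
  expect_gt(mean(phis), 0.95)
})

test_that("VB-EM improves the free energy and recovers AR coefficients roughly", {
  gen <- ar1_switching_model(f = c(0.90, 0.70), q = c(2, 10), r = 0.1)
  sim <- simulate_switching(gen, 400, seed = 61)
  set.seed(61)
  init <- switchssm:::draw_ar1_learning_init()
  fit <- suppressWarnings(
    vbem(init, sim$y, estep_config("interpolated"), em_config()))
  expect_gt(fit$f_trace[length(fit$f_trace)], fit$f_trace[1])
  f_learned <- sort(vapply(fit$model$ssms, function(s) s$F[1], numeric(1)),
                    decreasing = TRUE)
  expect_lt(abs(f_learned[1] - 0.90), 0.15)
  expect_lt(abs(f_learned[2] - 0.70), 0.15)
})

test_that("parameter recovery improves with data length", {
  err_at <- function(T_len, reps, seed0) {
    vapply(seq_len(reps), function(i) {
      gen <- ar1_switching_model(f = c(0.90, 0.70), q = c(2, 10), r = 0.1)
      sim <- simulate_switching(gen, T_len, seed = seed0 + i)
      init <- switchssm:::draw_ar1_learning_init()
      fit <- suppressWarnings(
        vbem(init, sim$y, estep_config("interpolated"), em_config()))
      fl <- vapply(fit$model$ssms, function(s) s$F[1], numeric(1))
      mean(abs(fl - c(0.90, 0.70)))
    }, numeric(1))
  }
  e200 <- err_at(200, 12, 8100)
  e1000 <- err_at(1000, 12, 8200)
  expect_lt(median(e1000), median(e200))
})

test_that("model serialization round-trips through JSON", {
  model <- bivariate_coupled_model(tied = FALSE)
  tf <- tempfile(fileext = ".json")
  write_model_json(model, tf)
  back <- read_model_json(tf)
  expect_equal(back$ssms[[1]]$F, model$ssms[[1]]$F, tolerance = 1e-12)
  expect_equal(back$R, model$R, tolerance = 1e-12)
  expect_equal(back$chain$phi, model$chain$phi, tolerance = 1e-12)
})
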