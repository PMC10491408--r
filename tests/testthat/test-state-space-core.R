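test_that("filter recovers observations under vanishing observation noise", {
  ssm <- gaussian_ssm(mu = 0, Q0 = matrix(1), F = matrix(0), Q = matrix(1),
                      G = matrix(1))
  y <- c(0.3, -1.2, 2.5, 0.1)
  f <- kalman_filter(ssm, y, R = matrix(1e-12))
  expect_lt(max(abs(f$x_filt[1, -1] - y)), 1e-6)
})

test_that("zero responsibility skips the measurement update exactly", {
  ssm <- random_scalar_ssm(42)
  set.seed(1); y <- rnorm(5)
  h <- c(1, 1, 0, 1, 1)
  f <- kalman_filter(ssm, y, R = matrix(0.4), h = h)
  expect_true(f$skipped[3])
  expect_identical(f$x_filt[, 4], f$x_pred[, 3])
  expect_identical(f$P_filt[, , 4], f$P_pred[, , 3])
  expect_identical(f$ll[3], 0)
})

test_that("unit responsibilities reproduce the plain filter bitwise", {
  ssm <- random_mv_ssm(7, d = 3, p = 2)
  set.seed(2); y <- matrix(rnorm(12), 6, 2)
  R <- diag(c(0.3, 0.5))
  f0 <- kalman_filter(ssm, y, R)
  f1 <- kalman_filter(ssm, y, R, h = rep(1, 6))
  expect_identical(f0$x_filt, f1$x_filt)
  expect_identical(f0$P_filt, f1$P_filt)
  expect_identical(f0$loglik, f1$loglik)
})

test_that("filter log-likelihood matches the dense joint-Gaussian oracle", {
  for (seed in c(3, 11, 29)) {
    ssm <- random_scalar_ssm(seed)
    R <- matrix(0.35)
    or <- joint_gaussian_oracle(ssm, R, 3)
    y <- draw_from_oracle(or, seed + 100)
    f <- kalman_filter(ssm, y, R)
    expect_equal(f$loglik, oracle_loglik(or, y), tolerance = 1e-8)
    expect_equal(f$loglik, sum(f$ll))
  }
  # multivariate state and bivariate observation
  ssm <- random_mv_ssm(5, d = 3, p = 2)
  R <- diag(c(0.4, 0.6))
  or <- joint_gaussian_oracle(ssm, R, 4)
  y <- draw_from_oracle(or, 500)
  expect_equal(kalman_filter(ssm, y, R)$loglik, oracle_loglik(or, y),
               tolerance = 1e-8)
})

test_that("smoother matches joint-Gaussian conditioning incl. lag-one terms", {
  for (cfg in list(list(seed = 13, d = 1, p = 1, T = 5),
                   list(seed = 17, d = 2, p = 1, T = 6),
                   list(seed = 23, d = 4, p = 2, T = 4))) {
    ssm <- if (cfg$d == 1) random_scalar_ssm(cfg$seed)
           else random_mv_ssm(cfg$seed, d = cfg$d, p = cfg$p)
    R <- 0.3 * diag(cfg$p)
    or <- joint_gaussian_oracle(ssm, R, cfg$T)
    y <- draw_from_oracle(or, cfg$seed + 1)
    sm <- rts_smooth(kalman_filter(ssm, y, R))
    os <- oracle_smoother(or, y)
    d <- cfg$d
    expect_equal(as.vector(sm$x_sm), as.vector(os$mean), tolerance = 1e-8)
    for (t in 0:cfg$T) {
      idx <- (t * d + 1):((t + 1) * d)
      expect_equal(sm$P_sm[, , t + 1], os$cov[idx, idx, drop = FALSE],
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
    for (t in seq_len(cfg$T)) {
      i1 <- (t * d + 1):((t + 1) * d)
      i0 <- ((t - 1) * d + 1):(t * d)
      expect_equal(sm$P_lag[, , t], os$cov[i1, i0, drop = FALSE],
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
    # boundary: smoothed == filtered at t = T
    f <- kalman_filter(ssm, y, R)
    expect_identical(sm$x_sm[, cfg$T + 1], f$x_filt[, cfg$T + 1])
    expect_identical(sm$P_sm[, , cfg$T + 1], f$P_filt[, , cfg$T + 1])
  }
})

test_that("returned covariances are numerically symmetric", {
  ssm <- random_mv_ssm(31, d = 3, p = 2)
  set.seed(4); y <- matrix(rnorm(16), 8, 2)
  sm <- rts_smooth(kalman_filter(ssm, y, 0.25 * diag(2)))
  asym <- function(A) max(abs(A - t(A)))
  for (t in 1:9) {
    expect_lt(asym(sm$P_sm[, , t]), 1e-10)
  }
})

test_that("interpolated density equals leave-one-out conditioning", {
  for (seed in c(41, 43)) {
    ssm <- random_scalar_ssm(seed)
    R <- matrix(0.3)
    or <- joint_gaussian_oracle(ssm, R, 6)
    y <- draw_from_oracle(or, seed + 7)
    expect_equal(interpolated_log_density(ssm, y, R),
                 oracle_interpolated(or, y), tolerance = 1e-8)
  }
  ssm <- random_mv_ssm(47, d = 2, p = 1)
  R <- matrix(0.5)
  or <- joint_gaussian_oracle(ssm, R, 6)
  y <- draw_from_oracle(or, 48)
  expect_equal(interpolated_log_density(ssm, y, R),
               oracle_interpolated(or, y), tolerance = 1e-8)
})

test_that("interpolated density handles the edge cases analytically", {
  # T = 1: prior predictive with empty conditioning set
  ssm <- gaussian_ssm(mu = 0.4, Q0 = matrix(2), F = matrix(0.7),
                      Q = matrix(1), G = matrix(1.3))
  R <- matrix(0.2)
  y <- matrix(0.9)
  v <- ssm$G[1]^2 * (ssm$F[1]^2 * ssm$Q0[1] + ssm$Q[1]) + R[1]
  m <- ssm$G[1] * ssm$F[1] * ssm$mu
  expect_equal(interpolated_log_density(ssm, y, R),
               dnorm(0.9, m, sqrt(v), log = TRUE), tolerance = 1e-10)
  # iid states (F = 0, Q0 = Q): every entry is the marginal density
  ssm2 <- gaussian_ssm(mu = 0, Q0 = matrix(1.5), F = matrix(0),
                       Q = matrix(1.5), G = matrix(2))
  set.seed(9); y2 <- rnorm(5)
  expect_equal(interpolated_log_density(ssm2, y2, R),
               dnorm(y2, 0, sqrt(4 * 1.5 + 0.2), log = TRUE),
               tolerance = 1e-10)
})

test_that("joint-Gaussian oracle basic identities", {
  ssm <- gaussian_ssm(mu = 0, Q0 = matrix(1.1), F = matrix(0.6),
                      Q = matrix(0.8), G = matrix(1.4))
  or <- joint_gaussian_oracle(ssm, matrix(0.25), 2)
  v1 <- or$cov[or$y_idx[[1]], or$y_idx[[1]]]
  expect_equal(v1, 1.4^2 * (0.6^2 * 1.1 + 0.8) + 0.25, tolerance = 1e-12)
  # F = 0 makes the observation block diagonal
  ssm0 <- gaussian_ssm(mu = 0, Q0 = matrix(1), F = matrix(0), Q = matrix(1),
                       G = matrix(1))
  or0 <- joint_gaussian_oracle(ssm0, matrix(0.1), 3)
  yi <- unlist(or0$y_idx)
  offdiag <- or0$cov[yi, yi]; diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 1e-12)
  expect_error(joint_gaussian_oracle(ssm, matrix(0.1), 1000), "refused")
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(gaussian_ssm(0, matrix(-1), matrix(0.5), matrix(1), matrix(1)),
               "positive semi-definite")
  ssm <- random_scalar_ssm(1)
  expect_error(kalman_filter(ssm, cbind(rnorm(3), rnorm(3)), matrix(1)),
               "mismatch")
  expect_error(kalman_filter(ssm, rnorm(3), matrix(1), h = c(1, 1)), "length")
  expect_error(kalman_filter(ssm, rnorm(3), matrix(1), h = c(1, 2, 1)),
               "\\[0, 1\\]")
})

test_that("stationary EM log-likelihood is non-decreasing", {
  ssm <- make_ar1(0.8, 1.5)
  set.seed(21)
  sim <- simulate_switching(
    switching_model(list(ssm), markov_chain(1, matrix(1)), matrix(0.3)),
    120, seed = 21)
  fit <- stationary_em(ssm, sim$y, R = matrix(0.3), n_iter = 15)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # starting at the truth, one iteration must not decrease the likelihood
  fit1 <- stationary_em(ssm, sim$y, R = matrix(0.3), n_iter = 2)
  expect_gte(fit1$loglik_trace[2], fit1$loglik_trace[1] - 1e-8)
})

test_that("two-oscillator EM initialization runs 50 iterations to finite values", {
  sim <- synthesize_sleep_eeg(duration_s = 10, fs = 100, seed = 77)
  init <- make_oscillator_ssm(list(
    oscillator_spec(0.98, 1, 100, 1, "slow"),
    oscillator_spec(0.98, 13, 100, 1, "spindle")), x0_var = 3)
  fit <- stationary_em(init, sim$y, R = matrix(1), n_iter = 50,
                       update_initial = FALSE)
  expect_true(all(is.finite(fit$loglik_trace)))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(all(is.finite(unlist(fit$ssm[c("F", "Q")]))))
  # initial state held fixed
  expect_identical(fit$ssm$mu, rep(0, 4))
  expect_identical(fit$ssm$Q0, 3 * diag(4))
})

test_that("observation reader round-trips single and two-column CSV", {
  tf <- tempfile(fileext = ".csv")
  y <- round(rnorm(20), 6)
  writeLines(format(y, trim = TRUE), tf)
  obs <- read_observations(tf, fs = 50)
  expect_equal(as.numeric(obs), y, tolerance = 1e-6)
  expect_equal(attr(obs, "fs"), 50)
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = (0:19) / 100, value = y), tf2,
                   row.names = FALSE)
  obs2 <- read_observations(tf2)
  expect_equal(attr(obs2, "fs"), 100, tolerance = 1e-9)
  expect_equal(as.numeric(obs2), y, tolerance = 1e-6)
})
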