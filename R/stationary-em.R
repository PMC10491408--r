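#' EM for a single (non-switching) Gaussian state-space model
#'
#' Classical maximum-likelihood EM: exact E-steps by Kalman filtering and RTS
#' smoothing, closed-form M-steps. For oscillator-structured models the
#' M-step preserves the rotation parameterization, updating each block's
#' damping `a`, frequency `omega`, and noise `sigma2` (optionally under
#' [map_priors()]). Used to initialize oscillator parameters before
#' switching inference: fit all components jointly as if present throughout,
#' then let the switching model decide when each is observed.
#'
#' @param ssm Initial `gaussian_ssm`.
#' @param y Observations.
#' @param R Initial observation-noise covariance (scalar or `p x p`).
#' @param n_iter Number of EM iterations (>= 1).
#' @param update_initial Update `mu` and `Q0`? The spindle pipeline holds the
#'   initial state at zero-mean noise and does not update it.
#' @param update_R Update the observation-noise covariance?
#' @param priors Optional [map_priors()] for MAP updates (oscillator models).
#' @return List of class `stationary_em_fit`: `ssm` (fitted), `R`,
#'   `loglik_trace` (log-likelihood at the start of each iteration, a
#'   non-decreasing sequence for ML updates), `smoother` (final `rts_result`).
#' @export
stationary_em <- function(ssm, y, R, n_iter = 50L, update_initial = TRUE,
                          update_R = TRUE, priors = NULL) {
  stopifnot(n_iter >= 1L)
  y <- as_observations(y)
  T_ <- nrow(y)
  p <- obs_dim(ssm)
  R <- as_cov(R, p, "R")
  cfg <- em_config(update = c(mu = update_initial, Q0 = update_initial,
                              F = TRUE, Q = TRUE, G = FALSE, R = update_R,
                              rho = FALSE, phi = FALSE),
                   priors = priors)
  trace <- numeric(n_iter)
  sm <- NULL
  for (i in seq_len(n_iter)) {
    filt <- kalman_filter(ssm, y, R)
    trace[i] <- filt$loglik
    if (!is.finite(trace[i]))
      stop("non-finite log-likelihood at EM iteration ", i)
    sm <- rts_smooth(filt)
    fake_post <- structure(
      list(h = matrix(1, T_, 1), p0 = 1,
           pairwise = array(1, c(1, 1, T_))),
      class = "markov_posterior")
    stats <- collect_stats(list(sm), fake_post, y)
    model <- switching_model(list(ssm), markov_chain(1, matrix(1)), R)
    model <- mstep(model, stats, cfg)
    ssm <- model$ssms[[1]]
    R <- model$R
  }
  structure(list(ssm = ssm, R = R, loglik_trace = trace, smoother = sm),
            class = "stationary_em_fit")
}
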