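#' Kalman filter with responsibility-scaled observation noise
#'
#' Runs the forward filtering recursion for a [gaussian_ssm()] under
#' observation noise covariance `R`, optionally scaled per time step by
#' responsibilities `h` so the effective noise at time `t` is `R / h[t]`. This
#' scaling is what couples each candidate model to the switching posterior in
#' the structured variational approximation: `h[t] = 1` recovers the ordinary
#' filter, while `h[t] -> 0` inflates the noise until the measurement update
#' is skipped (below `eps` it is skipped exactly and the filtered moments
#' equal the one-step predictions).
#'
#' @param ssm A `gaussian_ssm`.
#' @param y Observations (`T x p` matrix or numeric vector).
#' @param R Observation-noise covariance (`p x p` or scalar), must be
#'   positive definite.
#' @param h Optional length-`T` vector of responsibilities in \[0, 1\].
#' @param eps Threshold below which the measurement update is skipped.
#' @return An object of class `kf_result` with elements `x_filt`
#'   (`d x (T+1)`, columns `t = 0..T`), `P_filt` (`d x d x (T+1)`), `x_pred`,
#'   `P_pred` (one-step predictions for `t = 1..T`), per-step log-likelihood
#'   increments `ll`, their sum `loglik`, and the `skipped` indicator.
#' @export
kalman_filter <- function(ssm, y, R, h = NULL, eps = 1e-12) {
  y <- as_observations(y)
  p <- obs_dim(ssm)
  if (ncol(y) != p) stop("observation dimension mismatch: y has ", ncol(y),
                         " columns, model emits ", p)
  R <- as_cov(R, p, "R")
  T_ <- nrow(y)
  if (is.null(h)) {
    h <- rep(1, T_)
  } else {
    if (length(h) != T_) stop("h must have length T = ", T_)
    if (any(h < 0 | h > 1 + 1e-9)) stop("h entries must lie in [0, 1]")
  }
  out <- kf_cpp(ssm$mu, ssm$Q0, ssm$F, ssm$Q, ssm$G, R, y, h, eps)
  out$y <- y; out$R <- R; out$h <- h; out$ssm <- ssm
  out$ll <- drop(out$ll)
  out$skipped <- drop(out$skipped) > 0
  class(out) <- "kf_result"
  out
}

#' Rauch-Tung-Striebel smoother with lag-one covariances
#'
#' Backward pass over a [kalman_filter()] result giving the full-information
#' posterior moments \eqn{x_{t|T}}, \eqn{\Sigma_{t|T}} for `t = 0..T` and the
#' lag-one cross covariances \eqn{\Sigma_{t,t-1|T}} for `t = 1..T` needed by
#' the EM sufficient statistics.
#'
#' @param filt A `kf_result` from [kalman_filter()].
#' @return An object of class `rts_result` with `x_sm` (`d x (T+1)`), `P_sm`
#'   (`d x d x (T+1)`), `P_lag` (`d x d x T`, slice `t` holding
#'   \eqn{Cov(x_t, x_{t-1} | y_{1:T})}), plus the filter's log-likelihood
#'   pieces (`ll`, `loglik`, `skipped`, `h`, `R`) carried along for
#'   free-energy assembly.
#' @export
rts_smooth <- function(filt) {
  stopifnot(inherits(filt, "kf_result"))
  out <- rts_cpp(filt$ssm$F, filt$x_filt, filt$P_filt, filt$x_pred, filt$P_pred)
  out$ll <- filt$ll
  out$loglik <- filt$loglik
  out$skipped <- filt$skipped
  out$h <- filt$h
  out$R <- filt$R
  out$ssm <- filt$ssm
  out$y <- filt$y
  class(out) <- "rts_result"
  out
}

#' Leave-one-out (interpolated) predictive log-densities
#'
#' For each time `t`, computes \eqn{\log p(y_t \mid y_{1:t-1}, y_{t+1:T})}
#' under the model: the Gaussian predictive density of the held-out
#' observation given every other observation. Computed in O(T) by fusing the
#' forward one-step predictive with a backward information-filter likelihood
#' message, then integrating the observation equation. These densities are
#' the evidence initialization of the variational E-step.
#'
#' @inheritParams kalman_filter
#' @return Numeric vector of length `T`.
#' @export
interpolated_log_density <- function(ssm, y, R) {
  y <- as_observations(y)
  p <- obs_dim(ssm)
  if (ncol(y) != p) stop("observation dimension mismatch")
  R <- as_cov(R, p, "R")
  drop(interp_cpp(ssm$mu, ssm$Q0, ssm$F, ssm$Q, ssm$G, R, y))
}

#' Dense joint-Gaussian oracle for a linear-Gaussian SSM
#'
#' Builds the explicit joint mean and covariance of the stacked vector
#' `(x_0, ..., x_T, y_1, ..., y_T)` by direct propagation. Intended as an
#' independent test oracle for the filtering, smoothing, and interpolation
#' recursions on small instances; refuses problems beyond `max_size` total
#' dimensions.
#'
#' @inheritParams kalman_filter
#' @param T_len Number of observation time steps.
#' @param max_size Guard on the stacked dimension `(T+1) d + T p`.
#' @return List with `mean`, `cov`, and index helpers `x_idx` (list over
#'   `t = 0..T`) and `y_idx` (list over `t = 1..T`).
#' @export
joint_gaussian_oracle <- function(ssm, R, T_len, max_size = 200L) {
  d <- state_dim(ssm); p <- obs_dim(ssm)
  n <- (T_len + 1L) * d + T_len * p
  if (n > max_size) stop("oracle refused: stacked dimension ", n, " exceeds guard")
  R <- as_cov(R, p, "R")

  # state block first: means and covariances by propagation
  mx <- matrix(0, d, T_len + 1L)
  mx[, 1] <- ssm$mu
  for (t in seq_len(T_len)) mx[, t + 1] <- ssm$F %*% mx[, t]

  # Cov(x_s, x_t) = F^(s-t) Var(x_t) for s >= t
  V <- vector("list", T_len + 1L)
  V[[1]] <- ssm$Q0
  for (t in seq_len(T_len)) V[[t + 1]] <- ssm$F %*% V[[t]] %*% t(ssm$F) + ssm$Q
  Sx <- matrix(0, (T_len + 1L) * d, (T_len + 1L) * d)
  idx <- function(t) ((t) * d + 1L):((t + 1L) * d)  # t = 0..T
  for (t in 0:T_len) {
    Sx[idx(t), idx(t)] <- V[[t + 1]]
    if (t < T_len) {
      C <- V[[t + 1]]
      for (s in (t + 1):T_len) {
        C <- ssm$F %*% C  # Cov(x_s, x_t)
        Sx[idx(s), idx(t)] <- C
        Sx[idx(t), idx(s)] <- t(C)
      }
    }
  }

  # lift to (x, y): y_t = G x_t + v_t
  H <- matrix(0, T_len * p, (T_len + 1L) * d)
  for (t in seq_len(T_len)) H[((t - 1L) * p + 1L):(t * p), idx(t)] <- ssm$G
  mean_all <- c(as.vector(mx), as.vector(H %*% as.vector(mx)))
  cov_xy <- Sx %*% t(H)
  cov_yy <- H %*% Sx %*% t(H) + kronecker(diag(T_len), R)
  cov_all <- rbind(cbind(Sx, cov_xy), cbind(t(cov_xy), cov_yy))
  cov_all <- 0.5 * (cov_all + t(cov_all))

  nx <- (T_len + 1L) * d
  list(mean = mean_all, cov = cov_all,
       x_idx = lapply(0:T_len, function(t) idx(t)),
       y_idx = lapply(seq_len(T_len), function(t) nx + ((t - 1L) * p + 1L):(t * p)))
}
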