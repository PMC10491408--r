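#' Construct a linear-Gaussian state-space model
#'
#' A Gaussian SSM is parameterized by the initial state distribution
#' \eqn{x_0 \sim N(\mu, Q_0)}, linear dynamics \eqn{x_t = F x_{t-1} + w_t},
#' \eqn{w_t \sim N(0, Q)}, and an observation map \eqn{G} relating the hidden
#' state to observations \eqn{y_t = G x_t + v_t}. The observation noise
#' covariance \eqn{R} is *not* part of the model: in switching models it is
#' shared across candidate models and supplied alongside.
#'
#' The time origin convention is that \eqn{x_0} carries no observation; the
#' first observation is \eqn{y_1}.
#'
#' @param mu Initial state mean (length `d` numeric).
#' @param Q0 Initial state covariance (`d x d`, symmetric positive
#'   semi-definite).
#' @param F State-transition matrix (`d x d`).
#' @param Q State-noise covariance (`d x d`, symmetric positive semi-definite).
#' @param G Observation matrix (`p x d`).
#' @param blocks Optional list describing oscillator block structure (used by
#'   [make_oscillator_ssm()]); each element has `label`, `idx`, `a`, `omega`,
#'   `sigma2`.
#' @param fs Optional sampling rate in Hz, carried along for frequency
#'   conversions.
#' @return An object of class `gaussian_ssm`.
#' @seealso [make_ar1()], [make_oscillator_ssm()]
#' @export
gaussian_ssm <- function(mu, Q0, F, Q, G, blocks = NULL, fs = NULL) {
  mu <- as.numeric(mu)
  d <- length(mu)
  Q0 <- as_cov(Q0, d, "Q0")
  Q <- as_cov(Q, d, "Q")
  F <- as_sq(F, d, "F")
  G <- rbind(G)
  if (ncol(G) != d) stop("G must have ", d, " columns to match the state dimension")
  structure(
    list(mu = mu, Q0 = Q0, F = F, Q = Q, G = G, blocks = blocks, fs = fs),
    class = "gaussian_ssm"
  )
}

as_sq <- function(A, d, name) {
  A <- rbind(A)
  if (d == 1L && length(A) == 1L) A <- matrix(as.numeric(A), 1, 1)
  if (!all(dim(A) == c(d, d))) stop(name, " must be ", d, "x", d)
  storage.mode(A) <- "double"
  A
}

as_cov <- function(A, d, name) {
  A <- as_sq(A, d, name)
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
    stop(name, " must be symmetric")
  ev <- eigen(0.5 * (A + t(A)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop(name, " must be positive semi-definite")
  0.5 * (A + t(A))
}

state_dim <- function(ssm) length(ssm$mu)
obs_dim <- function(ssm) nrow(ssm$G)

#' @export
print.gaussian_ssm <- function(x, ...) {
  cat("<gaussian_ssm> state dim", state_dim(x), "| obs dim", obs_dim(x), "\n")
  if (!is.null(x$blocks)) {
    for (b in x$blocks) {
      f_hz <- if (!is.null(x$fs)) b$omega * x$fs / (2 * pi) else NA_real_
      cat(sprintf("  oscillator '%s': a=%.4f f=%.3f Hz sigma2=%.4g\n",
                  b$label, b$a, f_hz, b$sigma2))
    }
  }
  invisible(x)
}

#' Scalar AR(1) state-space model
#'
#' Builds the one-dimensional Gaussian SSM
#' \eqn{x_t = f x_{t-1} + w_t}, \eqn{w_t \sim N(0, q)}, observed directly
#' (`G = 1`). By default the initial state follows the stationary convention
#' used throughout the segmentation benchmarks: zero mean with the state-noise
#' variance (`mu = 0`, `Q0 = q`).
#'
#' @param f_coef AR coefficient. Values with `|f| >= 1` are accepted with a
#'   warning (the model is then non-stationary).
#' @param q State-noise variance (> 0).
#' @param mu,q0 Initial state mean and variance.
#' @return A `gaussian_ssm`.
#' @examples
#' make_ar1(0.99, 1)
#' @export
make_ar1 <- function(f_coef, q, mu = 0, q0 = q) {
  if (q <= 0) stop("state-noise variance q must be positive")
  if (abs(f_coef) >= 1) warning("|f_coef| >= 1: the AR(1) state is non-stationary")
  gaussian_ssm(mu = mu, Q0 = matrix(q0), F = matrix(f_coef),
               Q = matrix(q), G = matrix(1))
}

#' Specify a damped harmonic oscillator block
#'
#' An oscillator is a 2-D state (real and imaginary parts of a phasor) with
#' rotation dynamics \eqn{a R(\omega)} where \eqn{R(\omega)} is the rotation
#' matrix and \eqn{\omega = 2\pi f / f_s} radians per sample. Its projection on
#' the real axis generates a noisy oscillation at `f_hz`.
#'
#' @param a Damping factor in (0, 1].
#' @param f_hz Rotation frequency in Hz; must satisfy `0 <= f_hz < fs / 2`.
#' @param fs Sampling rate in Hz.
#' @param sigma2 Isotropic state-noise variance of the 2-D block.
#' @param label Optional block label; blocks with equal labels can be tied
#'   across candidate models during learning.
#' @return An object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(a, f_hz, fs, sigma2, label = NULL) {
  if (a <= 0 || a > 1) stop("damping a must lie in (0, 1]")
  if (f_hz < 0 || f_hz >= fs / 2)
    stop("f_hz must lie in [0, fs/2): frequency at or above Nyquist aliases")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  structure(list(a = a, f_hz = f_hz, fs = fs, sigma2 = sigma2,
                 omega = 2 * pi * f_hz / fs,
                 label = label %||% sprintf("osc_%g", f_hz)),
            class = "oscillator_spec")
}

rot_mat <- function(omega) {
  matrix(c(cos(omega), sin(omega), -sin(omega), cos(omega)), 2, 2)
}

#' Build a Gaussian SSM from oscillator blocks
#'
#' Stacks one or more oscillator blocks into a block-diagonal state-space
#' model. Each block contributes dynamics \eqn{a_j R(\omega_j)}, state noise
#' \eqn{\sigma_j^2 I_2}, and the row `[1 0]` of the observation matrix, so the
#' observation is the sum of the real parts of all blocks.
#'
#' @param specs A single [oscillator_spec()] or a list of them.
#' @param x0_var Initial state variance (isotropic) for every block; the
#'   initial mean is zero.
#' @return A `gaussian_ssm` carrying block metadata for structured learning.
#' @export
make_oscillator_ssm <- function(specs, x0_var = 3) {
  if (inherits(specs, "oscillator_spec")) specs <- list(specs)
  n <- length(specs)
  d <- 2L * n
  F <- matrix(0, d, d); Q <- matrix(0, d, d); G <- matrix(0, 1, d)
  blocks <- vector("list", n)
  for (j in seq_len(n)) {
    s <- specs[[j]]
    idx <- (2L * j - 1L):(2L * j)
    F[idx, idx] <- s$a * rot_mat(s$omega)
    Q[idx, idx] <- s$sigma2 * diag(2)
    G[1, idx[1]] <- 1
    blocks[[j]] <- list(label = s$label, idx = idx, a = s$a,
                        omega = s$omega, sigma2 = s$sigma2,
                        omega0 = s$omega)
  }
  gaussian_ssm(mu = rep(0, d), Q0 = x0_var * diag(d), F = F, Q = Q, G = G,
               blocks = blocks, fs = specs[[1]]$fs)
}

#' Coerce a series to the observation matrix convention
#'
#' Observations are stored as a `T x p` numeric matrix with an optional
#' sampling-rate attribute. Vectors become single-column matrices.
#'
#' @param y Numeric vector, matrix, or data frame of observations.
#' @param fs Optional sampling rate in Hz.
#' @return A `T x p` numeric matrix with attribute `fs`.
#' @export
as_observations <- function(y, fs = NULL) {
  if (is.data.frame(y)) y <- as.matrix(y)
  if (is.null(dim(y))) y <- matrix(as.numeric(y), ncol = 1)
  storage.mode(y) <- "double"
  if (nrow(y) < 1L) stop("need at least one observation")
  if (anyNA(y)) stop("missing values are not supported")
  attr(y, "fs") <- fs %||% attr(y, "fs")
  y
}

#' Read an observation series from CSV
#'
#' Accepts either a headerless single-column file of samples (supply `fs`), or
#' a two-column `time,value` file from which the sampling rate is inferred
#' from the median time step.
#'
#' @param path Path to a CSV file.
#' @param fs Sampling rate in Hz for single-column input.
#' @return Observations matrix as from [as_observations()].
#' @export
read_observations <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-+0-9.eE, \t]+$", first)
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) >= 2L) {
    tm <- as.numeric(df[[1]]); val <- as.numeric(df[[2]])
    dt <- stats::median(diff(tm))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time column")
    as_observations(val, fs = 1 / dt)
  } else {
    if (is.null(fs)) stop("single-column input requires an explicit fs")
    as_observations(as.numeric(df[[1]]), fs = fs)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
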