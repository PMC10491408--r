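#' E-step configuration
#'
#' @param init_mode How to initialize the fixed-point iterations:
#'   `"interpolated"` starts from leave-one-out predictive log-densities,
#'   `"annealed"` from equal responsibilities under a deterministic-annealing
#'   temperature schedule, `"given_g"` / `"given_h"` warm-start from supplied
#'   values.
#' @param center_evidence Subtract the time-mean from each candidate's
#'   initial evidence column. `NULL` (default) enables centering exactly when
#'   candidate models differ in state dimension, where richer models would
#'   otherwise be favored by their extra degrees of freedom.
#' @param max_iter Maximum number of fixed-point iterations.
#' @param h_tol Convergence tolerance on `max |h - h_prev|`.
#' @param f_tol Relative tolerance on the free-energy change.
#' @return An `estep_config` list.
#' @export
estep_config <- function(init_mode = c("interpolated", "annealed",
                                       "given_g", "given_h"),
                         center_evidence = NULL, max_iter = 50L,
                         h_tol = 1e-6, f_tol = 1e-8) {
  init_mode <- match.arg(init_mode)
  stopifnot(max_iter >= 1L, h_tol > 0, f_tol > 0)
  structure(list(init_mode = init_mode, center_evidence = center_evidence,
                 max_iter = as.integer(max_iter), h_tol = h_tol,
                 f_tol = f_tol),
            class = "estep_config")
}

#' Deterministic-annealing temperature schedule
#'
#' Temperatures start at `T0` and decay via `T_{i+1} = (T_i + 1) / 2`,
#' approaching 1 from above.
#'
#' @param T0 Initial temperature (>= 1).
#' @param n_steps Number of tempered iterations.
#' @return Numeric vector of temperatures, strictly decreasing toward 1.
#' @export
annealing_schedule <- function(T0 = 100, n_steps = 12L) {
  if (T0 < 1) stop("temperature must be >= 1")
  temps <- numeric(n_steps)
  temps[1] <- T0
  for (i in seq_len(n_steps - 1L)) temps[i + 1] <- (temps[i] + 1) / 2
  temps
}

#' Temperature-scale evidence and responsibilities
#'
#' Divides the model log-evidence and the responsibilities by the temperature
#' before their use in the fixed-point cycle; `temperature = 1` is the
#' identity.
#'
#' @param g Log-evidence matrix.
#' @param h Responsibility matrix.
#' @param temperature Temperature (>= 1).
#' @return List with scaled `g` and `h`.
#' @export
anneal_evidence <- function(g, h, temperature) {
  if (temperature < 1) stop("temperature must be >= 1")
  list(g = g / temperature, h = h / temperature)
}

#' Variational model log-evidence of one candidate
#'
#' Computes \eqn{g_t = -\frac12 [(y_t - G x_{t|T})' R^{-1} (y_t - G x_{t|T})
#' + Tr(R^{-1} G \Sigma_{t|T} G')]} from smoothed moments. The
#' \eqn{\log|2\pi R|} constant is omitted: it is common across candidates
#' because `R` is shared, and cancels in the switching posterior.
#'
#' @param ssm The candidate `gaussian_ssm`.
#' @param smoothed Its `rts_result`.
#' @param y Observations.
#' @param R Shared observation-noise covariance.
#' @return Numeric vector of length `T`.
#' @export
model_log_evidence <- function(ssm, smoothed, y, R) {
  y <- as_observations(y)
  p <- obs_dim(ssm)
  R <- as_cov(R, p, "R")
  Ri <- solve(R)
  T_ <- nrow(y)
  xs <- smoothed$x_sm[, -1, drop = FALSE]              # d x T, t = 1..T
  resid <- y - t(ssm$G %*% xs)                         # T x p
  quad <- rowSums((resid %*% Ri) * resid)
  W <- t(ssm$G) %*% Ri %*% ssm$G                       # d x d
  d <- state_dim(ssm)
  Pm <- matrix(smoothed$P_sm[, , -1, drop = FALSE], d * d, T_)
  tr <- as.numeric(crossprod(as.vector(W), Pm))
  -0.5 * (quad + tr)
}

#' Interpolated-density evidence initialization
#'
#' Column `m` holds the leave-one-out predictive log-densities
#' \eqn{\log p^{(m)}(y_t | y_{\setminus t})} of candidate `m`
#' (see [interpolated_log_density()]). Because these are normalized
#' densities, candidates with more hidden degrees of freedom are favored;
#' with `center = TRUE` each column is mean-centered over time so the
#' candidates compete on the shape of their evidence profile rather than its
#' level.
#'
#' @param model A `switching_model`.
#' @param y Observations.
#' @param center Logical, or `NULL` to center exactly when candidate state
#'   dimensions differ.
#' @return `T x M` matrix of initial log-evidence.
#' @export
init_evidence_interpolated <- function(model, y, center = NULL) {
  y <- as_observations(y)
  g <- vapply(model$ssms,
              function(s) interpolated_log_density(s, y, model$R),
              numeric(nrow(y)))
  g <- rbind(g)
  if (is.null(center)) {
    dims <- vapply(model$ssms, state_dim, 1L)
    center <- length(unique(dims)) > 1L
  }
  if (center) g <- sweep(g, 2, colMeans(g))
  g
}

smooth_all <- function(model, y, h_mat, eps = 1e-12) {
  lapply(seq_len(model$M), function(m)
    rts_smooth(kalman_filter(model$ssms[[m]], y, model$R,
                             h = h_mat[, m], eps = eps)))
}

evidence_all <- function(model, y, smoothers) {
  vapply(seq_len(model$M),
         function(m) model_log_evidence(model$ssms[[m]], smoothers[[m]],
                                        y, model$R),
         numeric(nrow(y)))
}

#' Negative variational free energy
#'
#' Assembles the lower bound \eqn{F(q, \theta)} on \eqn{\log p(y | \theta)}
#' from the pieces of one completed fixed-point pass: the h-weighted Kalman
#' log-likelihoods of the candidate smoothers, the HMM log-normalizer of the
#' evidence, and the `h'g` cross term. With a single candidate the expression
#' collapses to the exact Kalman log-likelihood.
#'
#' @param model A `switching_model`.
#' @param g `T x M` log-evidence the chain posterior was computed from.
#' @param h `T x M` responsibilities used for the candidate smoothers.
#' @param smoothers List of `rts_result`, one per candidate, produced with
#'   responsibilities `h`.
#' @param markov_post The `markov_posterior` from [forward_backward()] on `g`.
#' @return Scalar free energy.
#' @export
negative_free_energy <- function(model, g, h, smoothers, markov_post) {
  T_ <- nrow(g); p <- model$p
  if (!all(dim(g) == dim(h))) stop("g and h must have equal dimensions")
  ld2piR <- p * log(2 * pi) +
    as.numeric(determinant(model$R, logarithm = TRUE)$modulus)
  total <- -T_ / 2 * ld2piR + markov_post$logZ - sum(h * g)
  for (m in seq_len(model$M)) {
    sm <- smoothers[[m]]
    if (length(sm$ll) != T_) stop("smoother and evidence lengths disagree")
    ct <- ifelse(sm$skipped, 0,
                 sm$ll + 0.5 * ld2piR - (p / 2) * log(sm$h))
    total <- total + sum(ct)
  }
  total
}

#' Structured variational E-step by fixed-point iterations
#'
#' Iterates the four-step cycle that makes the chain posterior and the
#' candidate-state posteriors consistent: (1) forward-backward on the current
#' evidence `g`, (2) responsibilities `h` from the chain marginals, (3)
#' per-candidate Kalman/RTS smoothing with effective noise `R / h_t`, (4)
#' fresh evidence from the smoothed moments. Iterations stop when `h` has
#' stabilized and the free energy change is below tolerance, when the free
#' energy stops increasing, or at `max_iter`.
#'
#' Initialization follows `cfg$init_mode`: interpolated densities enter the
#' cycle at step (1); deterministic annealing enters at step (3) with equal
#' responsibilities and temperature-scaled `g` and `h` (the free-energy trace
#' is diagnostic while the temperature exceeds 1); warm starts enter with the
#' supplied `g` or `h`.
#'
#' @param model A `switching_model`.
#' @param y Observations.
#' @param cfg An [estep_config()].
#' @param anneal Temperature vector from [annealing_schedule()], required for
#'   `init_mode = "annealed"`.
#' @param g_init,h_init Warm-start values for the respective modes.
#' @return Object of class `vb_estep`: `g`, `h` (`T x M`), `markov`
#'   (the `markov_posterior`), `smoothers` (list of `rts_result`),
#'   `free_energy`, `free_energy_trace`, `n_iter`, `converged`.
#' @export
fixed_point_estep <- function(model, y, cfg = estep_config(), anneal = NULL,
                              g_init = NULL, h_init = NULL) {
  y <- as_observations(y)
  T_ <- nrow(y); M <- model$M

  temps <- rep(1, cfg$max_iter)
  if (cfg$init_mode == "annealed") {
    if (is.null(anneal)) anneal <- annealing_schedule()
    k <- min(length(anneal), cfg$max_iter)
    temps[seq_len(k)] <- anneal[seq_len(k)]
  }

  g <- NULL; h <- NULL
  if (cfg$init_mode == "interpolated") {
    g <- init_evidence_interpolated(model, y, center = cfg$center_evidence)
  } else if (cfg$init_mode == "given_g") {
    if (is.null(g_init)) stop("init_mode 'given_g' requires g_init")
    g <- rbind(g_init)
  } else if (cfg$init_mode == "given_h") {
    if (is.null(h_init)) stop("init_mode 'given_h' requires h_init")
    h <- rbind(h_init)
  } else {
    h <- if (is.null(h_init)) matrix(1 / M, T_, M) else rbind(h_init)
  }

  f_trace <- numeric(0)
  markov <- NULL; smoothers <- NULL
  h_prev <- NULL; f_prev <- -Inf
  converged <- FALSE
  n_iter <- 0L

  for (i in seq_len(cfg$max_iter)) {
    n_iter <- i
    tv <- temps[i]
    if (!is.null(g)) {
      markov <- forward_backward(g / tv, model$chain)
      h <- markov$h
    }
    h_eff <- h / tv
    smoothers <- smooth_all(model, y, h_eff)
    if (!is.null(markov)) {
      f_cur <- negative_free_energy(model, g / tv, h, smoothers, markov)
      if (!is.finite(f_cur))
        stop("non-finite free energy at fixed-point iteration ", i)
      f_trace <- c(f_trace, f_cur)
      if (tv == 1 && !is.null(h_prev)) {
        dh <- max(abs(h - h_prev))
        df <- abs(f_cur - f_prev) / max(1, abs(f_cur))
        if (dh < cfg$h_tol && df < cfg$f_tol) converged <- TRUE
        if (f_cur < f_prev - 1e-10 * max(1, abs(f_prev))) converged <- TRUE
      }
      f_prev <- f_cur
      h_prev <- h
    }
    g <- evidence_all(model, y, smoothers)
    if (converged) break
  }

  if (is.null(markov)) {  # single tempered pass without a chain update yet
    markov <- forward_backward(g, model$chain)
    h <- markov$h
  }

  structure(list(g = g, h = h, markov = markov, smoothers = smoothers,
                 free_energy = if (length(f_trace)) f_trace[length(f_trace)] else NA_real_,
                 free_energy_trace = f_trace, n_iter = n_iter,
                 converged = converged, model = model, y = y),
            class = "vb_estep")
}

#' @export
print.vb_estep <- function(x, ...) {
  cat("<vb_estep>", ncol(x$h), "candidates,", nrow(x$h), "time points;",
      x$n_iter, "fixed-point iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  free energy:", format(x$free_energy), "\n")
  invisible(x)
}
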