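#' Assemble a switching state-space model
#'
#' A switching model is a pool of `M` candidate [gaussian_ssm()] models whose
#' hidden states evolve independently and in parallel, a [markov_chain()]
#' selecting which candidate emits each observation, and an observation-noise
#' covariance `R` shared across candidates.
#'
#' @param ssms List of `M` `gaussian_ssm` objects sharing one observation
#'   dimension.
#' @param chain A `markov_chain` with `M` states.
#' @param R Shared observation-noise covariance (`p x p` or scalar).
#' @param tying Optional [tying_spec()] declaring parameters shared across
#'   candidates during learning.
#' @return An object of class `switching_model`.
#' @export
switching_model <- function(ssms, chain, R, tying = NULL) {
  if (inherits(ssms, "gaussian_ssm")) ssms <- list(ssms)
  M <- length(ssms)
  if (M < 1L) stop("need at least one candidate model")
  p <- obs_dim(ssms[[1]])
  if (!all(vapply(ssms, obs_dim, 1L) == p))
    stop("all candidate models must share one observation dimension")
  if (chain$M != M) stop("chain has ", chain$M, " states but there are ", M, " models")
  R <- as_cov(R, p, "R")
  structure(list(ssms = ssms, chain = chain, R = R, tying = tying,
                 M = M, p = p),
            class = "switching_model")
}

#' @export
print.switching_model <- function(x, ...) {
  cat("<switching_model>", x$M, "candidate models, obs dim", x$p, "\n")
  for (m in seq_len(x$M))
    cat(sprintf("  [%d] state dim %d\n", m, state_dim(x$ssms[[m]])))
  if (!is.null(x$tying)) cat("  tying:", format(x$tying), "\n")
  invisible(x)
}

#' Declare parameters shared across candidate models
#'
#' Two tying mechanisms are supported, matching the two study designs that
#' need them:
#' * `F_ids`: element-level sharing of state-transition matrices. A list of
#'   `M` integer matrices shaped like each model's `F`; equal positive ids
#'   share one estimated value (possibly across models), `NA` entries are held
#'   fixed at their current value. Used together with `Q_groups`, a list of
#'   integer vectors naming models whose `Q` is pooled into one estimate.
#' * `share_blocks`: for oscillator-structured models, a character vector of
#'   block labels whose parameters `(a, omega, sigma2)` are pooled across all
#'   candidates carrying that label.
#'
#' @param F_ids Optional list of id matrices (element-masked `F` sharing).
#' @param Q_groups Optional list of integer vectors of model indices pooling
#'   their state-noise covariance.
#' @param share_blocks Optional character vector of oscillator block labels.
#' @return An object of class `tying_spec`.
#' @export
tying_spec <- function(F_ids = NULL, Q_groups = NULL, share_blocks = NULL) {
  structure(list(F_ids = F_ids, Q_groups = Q_groups,
                 share_blocks = share_blocks),
            class = "tying_spec")
}

#' @export
format.tying_spec <- function(x, ...) {
  parts <- c(
    if (!is.null(x$F_ids)) "element-tied F",
    if (!is.null(x$Q_groups)) "pooled Q",
    if (!is.null(x$share_blocks))
      paste0("shared blocks {", paste(x$share_blocks, collapse = ", "), "}")
  )
  paste(parts, collapse = " + ")
}

#' Nested oscillator candidate set
#'
#' Given `n` oscillator specifications, builds the switching model whose
#' `2^n - 1` candidates are all nonempty subsets of the oscillators: candidate
#' states stack the chosen blocks and the observation matrix sums their real
#' parts. Models the situation where a signal contains different combinations
#' of oscillations at different times.
#'
#' @param specs List of up to 5 [oscillator_spec()] objects.
#' @param R Shared observation-noise variance.
#' @param rho Initial switch distribution (default uniform).
#' @param diag_p Self-transition probability of the switching chain.
#' @param x0_var Initial state variance per block.
#' @return A `switching_model` with `2^n - 1` candidates; attribute `subsets`
#'   records which oscillators each candidate contains.
#' @export
build_nested_oscillator_models <- function(specs, R, rho = NULL,
                                           diag_p = 0.98, x0_var = 3) {
  if (inherits(specs, "oscillator_spec")) specs <- list(specs)
  n <- length(specs)
  if (n < 1L || n > 5L) stop("between 1 and 5 oscillators are supported")
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  # order subsets by size then lexicographically, single oscillators first
  ssms <- lapply(subsets, function(ss) make_oscillator_ssm(specs[ss], x0_var))
  M <- length(ssms)
  chain <- markov_chain(rho %||% rep(1 / M, M), phi_diag(M, diag_p))
  out <- switching_model(ssms, chain, R,
                         tying = tying_spec(share_blocks =
                           vapply(specs, function(s) s$label, character(1))))
  attr(out, "subsets") <- subsets
  out
}

#' Two-candidate spindle model (slow alone vs slow + spindle)
#'
#' Builds the sleep-spindle switching model: candidate 1 stacks a slow
#' oscillator and a spindle oscillator (`G = [1 0 1 0]`); candidate 2 carries
#' the slow oscillator only (`G = [1 0]`). The slow block is tied across the
#' two candidates, reflecting the assumption that slow-wave background
#' dynamics are stationary whether or not a spindle is present.
#'
#' @param slow,spindle [oscillator_spec()] for the slow (delta) and spindle
#'   (sigma) oscillations; `slow$f_hz < spindle$f_hz` is required.
#' @param r Shared observation-noise variance.
#' @param diag_p Self-transition probability (default 0.99: spindles are
#'   infrequent relative to the sampling rate).
#' @param x0_var Initial state variance per block.
#' @return A `switching_model` with slow-block tying.
#' @export
build_spindle_model <- function(slow, spindle, r, diag_p = 0.99, x0_var = 3) {
  if (slow$f_hz >= spindle$f_hz)
    stop("the slow oscillator must be below the spindle oscillator in frequency")
  slow$label <- "slow"; spindle$label <- "spindle"
  m1 <- make_oscillator_ssm(list(slow, spindle), x0_var)
  m2 <- make_oscillator_ssm(list(slow), x0_var)
  chain <- markov_chain(c(0.5, 0.5), phi_diag(2, diag_p))
  switching_model(list(m1, m2), chain, R = matrix(r),
                  tying = tying_spec(share_blocks = "slow"))
}

#' Simulate from a switching state-space model
#'
#' Draws a switch path from the chain (starting at `s_0 ~ rho`, one
#' transition before the first emission), evolves every candidate model's
#' hidden state in parallel for all `t`, and emits
#' `y_t = G^(s_t) x_t^(s_t) + v_t` with `v_t ~ N(0, R)`.
#'
#' @param model A `switching_model`.
#' @param T_len Number of observations.
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `switching_sim`: `y` (`T x p`), `s` (length `T`,
#'   the emitting model per time step; `s0` kept separately), `x` (list of
#'   `d_m x (T+1)` state trajectories), and `seed`.
#' @export
simulate_switching <- function(model, T_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- model$M; p <- model$p
  cR <- chol_psd(model$R)

  s <- integer(T_len + 1L)
  s[1] <- sample.int(M, 1L, prob = model$chain$rho)
  for (t in seq_len(T_len))
    s[t + 1] <- sample.int(M, 1L, prob = model$chain$phi[, s[t]])

  x <- vector("list", M)
  for (m in seq_len(M)) {
    ssm <- model$ssms[[m]]
    d <- state_dim(ssm)
    xm <- matrix(0, d, T_len + 1L)
    xm[, 1] <- ssm$mu + chol_psd(ssm$Q0) %*% stats::rnorm(d)
    cQ <- chol_psd(ssm$Q)
    for (t in seq_len(T_len))
      xm[, t + 1] <- ssm$F %*% xm[, t] + cQ %*% stats::rnorm(d)
    x[[m]] <- xm
  }

  y <- matrix(0, T_len, p)
  for (t in seq_len(T_len)) {
    m <- s[t + 1]
    y[t, ] <- model$ssms[[m]]$G %*% x[[m]][, t + 1] + cR %*% stats::rnorm(p)
  }

  structure(list(y = as_observations(y), s = s[-1], s0 = s[1], x = x,
                 seed = seed),
            class = "switching_sim")
}

# lower-triangular factor tolerant of PSD matrices
chol_psd <- function(A) {
  A <- 0.5 * (A + t(A))
  ok <- tryCatch(t(chol(A)), error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  e <- eigen(A, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(A)) %*% t(e$vectors)
}

#' Fraction of time points segmented correctly
#'
#' Compares estimated switch labels with the ground-truth path. Probabilities
#' are converted to labels by a 0.5 threshold on the first column for `M = 2`
#' and by the row argmax otherwise. `permute = TRUE` scores the best label
#' permutation (useful when candidate identity is not anchored).
#'
#' @param est Either an integer label vector of length `T` or a `T x M`
#'   matrix of model probabilities.
#' @param truth Integer vector of true states (length `T`).
#' @param threshold Probability threshold for the binary case.
#' @param permute Score the best permutation of labels.
#' @return Fraction in \[0, 1\].
#' @export
segmentation_accuracy <- function(est, truth, threshold = 0.5, permute = FALSE) {
  truth <- as.integer(truth)
  if (is.matrix(est)) {
    M <- ncol(est)
    est <- if (M == 2L) ifelse(est[, 1] >= threshold, 1L, 2L)
           else max.col(est, ties.method = "first")
  }
  est <- as.integer(est)
  if (length(est) != length(truth)) stop("label vectors differ in length")
  if (!permute) return(mean(est == truth))
  M <- max(truth, est)
  perms <- all_perms(M)
  max(vapply(perms, function(pp) mean(pp[est] == truth), numeric(1)))
}

all_perms <- function(M) {
  if (M == 1L) return(list(1L))
  sub <- all_perms(M - 1L)
  out <- list()
  for (s in sub) for (k in seq_len(M)) out <- c(out, list(append(s, M, after = k - 1L)))
  out
}
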