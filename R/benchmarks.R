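#' Two-model AR(1) switching benchmark model
#'
#' The canonical two-candidate benchmark: scalar AR(1) models with
#' coefficients `f` and state-noise variances `q`, observed directly under
#' shared noise variance `r`, switched by a sticky binary chain.
#'
#' @param f,q Length-2 AR coefficients and state-noise variances.
#' @param r Observation-noise variance.
#' @param diag_p Chain self-transition probability.
#' @return A `switching_model`.
#' @export
ar1_switching_model <- function(f = c(0.99, 0.90), q = c(1, 10), r = 0.1,
                                diag_p = 0.95) {
  ssms <- Map(function(fi, qi) make_ar1(fi, qi), f, q)
  switching_model(ssms, markov_chain(rep(1 / length(f), length(f)),
                                     phi_diag(length(f), diag_p)),
                  R = matrix(r))
}

#' Candidate pair for the coupled bivariate AR(1) study
#'
#' Two 2-D candidates identical except for the `F[1,2]` coupling element,
#' which is `f12` in candidate 1 and 0 in candidate 2: the second series
#' drives the first only while the chain sits in state 1. When
#' `tied = TRUE`, the tying specification shares every estimated parameter
#' across the candidates except `F[1,2]` of candidate 1 (candidate 2's
#' coupling stays fixed at 0), and pools the state-noise covariance.
#'
#' @param f_diag Diagonal AR coefficient.
#' @param f12 Coupling strength in candidate 1.
#' @param q State-noise variance (isotropic).
#' @param r Observation-noise variance (isotropic).
#' @param diag_p Chain self-transition probability.
#' @param tied Attach the shared-parameter tying specification.
#' @return A `switching_model`.
#' @export
bivariate_coupled_model <- function(f_diag = 0.5, f12 = 0.5, q = 2, r = 0.1,
                                    diag_p = 0.95, tied = TRUE) {
  F1 <- matrix(c(f_diag, 0, f12, f_diag), 2, 2)
  F2 <- diag(c(f_diag, f_diag))
  Q <- q * diag(2)
  m1 <- gaussian_ssm(c(0, 0), Q, F1, Q, diag(2))
  m2 <- gaussian_ssm(c(0, 0), Q, F2, Q, diag(2))
  tying <- if (tied) {
    # column-major ids over F = [F11 F12; F21 F22]; NA entries stay fixed
    tying_spec(F_ids = list(matrix(c(1, NA, 3, 2), 2, 2),
                            matrix(c(1, NA, NA, 2), 2, 2)),
               Q_groups = list(1:2))
  } else NULL
  switching_model(list(m1, m2),
                  markov_chain(c(0.5, 0.5), phi_diag(2, diag_p)),
                  R = r * diag(2), tying = tying)
}

#' Simulate the coupled bivariate AR(1) generative process
#'
#' A *single* bivariate AR(1) state whose `F[1,2]` element switches between
#' `f12` and 0 along a hidden binary chain; both components are observed in
#' noise. Note the deliberate model-class mismatch with
#' [bivariate_coupled_model()]: the generative process has one state vector,
#' the inference model uses two parallel candidates.
#'
#' @inheritParams bivariate_coupled_model
#' @param T_len Series length.
#' @param seed Optional seed.
#' @return A `switching_sim` (states stored as the single trajectory).
#' @export
simulate_bivariate_coupled <- function(T_len, f_diag = 0.5, f12 = 0.5, q = 2,
                                       r = 0.1, diag_p = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chain <- markov_chain(c(0.5, 0.5), phi_diag(2, diag_p))
  s <- integer(T_len + 1L)
  s[1] <- sample.int(2L, 1L, prob = chain$rho)
  for (t in seq_len(T_len)) s[t + 1] <- sample.int(2L, 1L, prob = chain$phi[, s[t]])
  Fs <- list(matrix(c(f_diag, 0, f12, f_diag), 2, 2), diag(c(f_diag, f_diag)))
  x <- matrix(0, 2, T_len + 1L)
  x[, 1] <- sqrt(q) * stats::rnorm(2)
  for (t in seq_len(T_len))
    x[, t + 1] <- Fs[[s[t + 1]]] %*% x[, t] + sqrt(q) * stats::rnorm(2)
  y <- t(x[, -1, drop = FALSE]) + sqrt(r) * matrix(stats::rnorm(2 * T_len), T_len, 2)
  structure(list(y = as_observations(y), s = s[-1], s0 = s[1], x = list(x),
                 seed = seed),
            class = "switching_sim")
}

#' Simulate switching combinations of shared oscillations
#'
#' `n` oscillators evolve continuously; a multinomial chain over the
#' `2^n - 1` nonempty subsets decides which oscillations are *observed* at
#' each time step. This is the generative process behind the nested
#' candidate sets of [build_nested_oscillator_models()].
#'
#' @param model A nested-oscillator `switching_model` (carries the subset
#'   bookkeeping).
#' @param specs The oscillator specifications used to build `model`.
#' @param T_len Series length.
#' @param seed Optional seed.
#' @return A `switching_sim`; `x` holds one trajectory per oscillator.
#' @export
simulate_nested_oscillators <- function(model, specs, T_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subsets <- attr(model, "subsets")
  if (is.null(subsets)) stop("model does not carry nested-subset bookkeeping")
  n <- length(specs)
  chain <- model$chain
  M <- chain$M
  s <- integer(T_len + 1L)
  s[1] <- sample.int(M, 1L, prob = chain$rho)
  for (t in seq_len(T_len)) s[t + 1] <- sample.int(M, 1L, prob = chain$phi[, s[t]])
  x <- vector("list", n)
  for (j in seq_len(n)) {
    sp <- specs[[j]]
    Fb <- sp$a * rot_mat(sp$omega)
    xj <- matrix(0, 2, T_len + 1L)
    xj[, 1] <- sqrt(3) * stats::rnorm(2)
    for (t in seq_len(T_len))
      xj[, t + 1] <- Fb %*% xj[, t] + sqrt(sp$sigma2) * stats::rnorm(2)
    x[[j]] <- xj
  }
  r <- model$R[1, 1]
  y <- matrix(0, T_len, 1)
  for (t in seq_len(T_len)) {
    obs <- sum(vapply(subsets[[s[t + 1]]], function(j) x[[j]][1, t + 1],
                      numeric(1)))
    y[t, 1] <- obs + sqrt(r) * stats::rnorm(1)
  }
  structure(list(y = as_observations(y, fs = specs[[1]]$fs), s = s[-1],
                 s0 = s[1], x = x, seed = seed),
            class = "switching_sim")
}

label_from_estep <- function(est, threshold = 0.5) {
  h <- est$h
  if (ncol(h) == 2L) ifelse(h[, 1] >= threshold, 1L, 2L)
  else max.col(h, ties.method = "first")
}

draw_ar1_learning_init <- function() {
  f1 <- stats::runif(1, 0.8, 1.0); f2 <- stats::runif(1, 0.6, 0.8)
  q1 <- stats::runif(1, 1, 3); q2 <- stats::runif(1, 5, 15)
  r <- stats::runif(1, 0.01, 0.2)
  pd <- stats::runif(1, 0.9, 0.99)
  ar1_switching_model(f = c(f1, f2), q = c(q1, q2), r = r, diag_p = pd)
}

draw_bivariate_learning_init <- function() {
  f11 <- stats::runif(1, 0.4, 0.6); f22 <- stats::runif(1, 0.4, 0.6)
  f12 <- stats::runif(1, 0.4, 0.6)
  q11 <- stats::runif(1, 1, 3); q22 <- stats::runif(1, 1, 3)
  r11 <- stats::runif(1, 0.01, 0.2); r22 <- stats::runif(1, 0.01, 0.2)
  pd <- stats::runif(1, 0.9, 0.99)
  F1 <- matrix(c(f11, 0, f12, f22), 2, 2)
  F2 <- diag(c(f11, f22))
  Q <- diag(c(q11, q22))
  m1 <- gaussian_ssm(c(0, 0), Q, F1, Q, diag(2))
  m2 <- gaussian_ssm(c(0, 0), Q, F2, Q, diag(2))
  switching_model(list(m1, m2), markov_chain(c(0.5, 0.5), phi_diag(2, pd)),
                  R = diag(c(r11, r22)),
                  tying = tying_spec(F_ids = list(matrix(c(1, NA, 3, 2), 2, 2),
                                                  matrix(c(1, NA, NA, 2), 2, 2)),
                                     Q_groups = list(1:2)))
}

#' Run a segmentation benchmark study
#'
#' Reproduces one of the Monte-Carlo segmentation studies end to end:
#' simulate `reps` sequences from the study's generative process, run each
#' inference method, and score segmentation accuracy against the true switch
#' path (0.5 threshold for two candidates, argmax otherwise).
#'
#' Studies:
#' * `"ar1_inference"`: two AR(1) candidates (`F = 0.99, 0.90`;
#'   `Q = 1, 10`; `R = 0.1`; chain diagonal 0.95), true parameters; methods
#'   `random`, `static`, `imm`, `vi_a` (annealed, temperature 100 over 12
#'   iterations), `vi_i` (interpolated, 12 iterations).
#' * `"ar1_learning"`: AR(1) generative model (`F = 0.90, 0.70`;
#'   `Q = 2, 10`; `R = 0.1`); per-sequence random initial parameters from
#'   uniform ranges around the truth; `static`/`imm` use the random draws
#'   as-is, `vi_a_em`/`vi_i_em` learn by generalized EM until convergence.
#' * `"bivariate"`: coupled bivariate AR(1) generative process with switching
#'   `F[1,2]`, true-parameter inference run to convergence.
#' * `"bivariate_learning"`: same data; random initial parameters; VB-EM
#'   with all parameters except candidate 1's coupling tied across models.
#' * `"oscillators"`: nested oscillator candidate sets for `n = 2..5`
#'   underlying oscillations (3..31 candidates), true parameters, E-step
#'   only, evidence mean-centering on.
#'
#' @param name Study name.
#' @param reps Number of simulated sequences.
#' @param T_len Sequence length (`"oscillators"` uses 10 s at 100 Hz).
#' @param seed Master seed; per-sequence seeds are spawned from it.
#' @param methods Optional subset of the study's methods.
#' @param n_osc Oscillator counts for the `"oscillators"` study.
#' @return A tibble with columns `rep`, `method`, `accuracy` (and `n_osc`
#'   for the oscillator study), with a `summary` attribute of per-method
#'   means and standard errors.
#' @export
run_benchmark <- function(name = c("ar1_inference", "ar1_learning",
                                   "bivariate", "bivariate_learning",
                                   "oscillators"),
                          reps = 200L, T_len = 200L, seed = 1L,
                          methods = NULL, n_osc = 2:5) {
  name <- match.arg(name)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, reps)
  rows <- switch(
    name,
    ar1_inference = bench_ar1_inference(reps, T_len, rep_seeds, methods),
    ar1_learning = bench_ar1_learning(reps, T_len, rep_seeds, methods),
    bivariate = bench_bivariate(reps, T_len, rep_seeds, methods, learn = FALSE),
    bivariate_learning = bench_bivariate(reps, T_len, rep_seeds, methods,
                                         learn = TRUE),
    oscillators = bench_oscillators(reps, rep_seeds, methods, n_osc)
  )
  out <- dplyr::bind_rows(rows)
  grp <- if ("n_osc" %in% names(out)) c("method", "n_osc") else "method"
  summ <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sem = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop")
  attr(out, "summary") <- summ
  out
}

bench_ar1_inference <- function(reps, T_len, rep_seeds, methods) {
  model <- ar1_switching_model()
  methods <- methods %||% c("random", "static", "imm", "vi_a", "vi_i")
  purrr::map(seq_len(reps), function(i) {
    sim <- simulate_switching(model, T_len, seed = rep_seeds[i])
    acc <- run_inference_methods(model, sim, methods, n_fp = 12L)
    tibble::tibble(rep = i, method = names(acc), accuracy = unname(acc))
  })
}

run_inference_methods <- function(model, sim, methods, n_fp = 50L,
                                  center = NULL) {
  vapply(methods, function(meth) {
    switch(meth,
      random = segmentation_accuracy(
        random_segmentation(length(sim$s), model$M), sim$s),
      static = segmentation_accuracy(static_switching(model, sim$y)$probs, sim$s),
      imm = segmentation_accuracy(imm(model, sim$y)$probs, sim$s),
      vi_a = {
        est <- fixed_point_estep(model, sim$y,
                                 estep_config("annealed", max_iter = n_fp),
                                 anneal = annealing_schedule(100, 12L))
        segmentation_accuracy(label_from_estep(est), sim$s)
      },
      vi_i = {
        est <- fixed_point_estep(model, sim$y,
                                 estep_config("interpolated", max_iter = n_fp,
                                              center_evidence = center))
        segmentation_accuracy(label_from_estep(est), sim$s)
      },
      stop("unknown method ", meth))
  }, numeric(1))
}

bench_ar1_learning <- function(reps, T_len, rep_seeds, methods) {
  gen <- ar1_switching_model(f = c(0.90, 0.70), q = c(2, 10), r = 0.1,
                             diag_p = 0.95)
  methods <- methods %||% c("random", "static", "imm", "vi_a_em", "vi_i_em")
  purrr::map(seq_len(reps), function(i) {
    sim <- simulate_switching(gen, T_len, seed = rep_seeds[i])
    init <- draw_ar1_learning_init()
    acc <- run_learning_methods(init, sim, methods)
    tibble::tibble(rep = i, method = names(acc), accuracy = unname(acc))
  })
}

run_learning_methods <- function(init, sim, methods, mcfg = em_config()) {
  vapply(methods, function(meth) {
    switch(meth,
      random = segmentation_accuracy(
        random_segmentation(length(sim$s), init$M), sim$s),
      static = segmentation_accuracy(static_switching(init, sim$y)$probs, sim$s),
      imm = segmentation_accuracy(imm(init, sim$y)$probs, sim$s),
      vi_a_em = {
        fit <- vbem(init, sim$y, estep_config("annealed"), mcfg,
                    anneal = annealing_schedule(100, 12L))
        segmentation_accuracy(label_from_estep(fit$estep), sim$s)
      },
      vi_i_em = {
        fit <- vbem(init, sim$y, estep_config("interpolated"), mcfg)
        segmentation_accuracy(label_from_estep(fit$estep), sim$s)
      },
      stop("unknown method ", meth))
  }, numeric(1))
}

bench_bivariate <- function(reps, T_len, rep_seeds, methods, learn) {
  methods <- methods %||% if (learn) c("random", "static", "imm", "vi_a_em",
                                       "vi_i_em")
                          else c("random", "static", "imm", "vi_a", "vi_i")
  purrr::map(seq_len(reps), function(i) {
    sim <- simulate_bivariate_coupled(T_len, seed = rep_seeds[i])
    if (learn) {
      init <- draw_bivariate_learning_init()
      acc <- run_learning_methods(init, sim, methods)
    } else {
      model <- bivariate_coupled_model(tied = FALSE)
      acc <- run_inference_methods(model, sim, methods, n_fp = 50L)
    }
    tibble::tibble(rep = i, method = names(acc), accuracy = unname(acc))
  })
}

bench_oscillators <- function(reps, rep_seeds, methods, n_osc) {
  methods <- methods %||% c("vi_a", "vi_i")
  freqs <- c(1, 10, 20, 30, 40)
  purrr::map(n_osc, function(n) {
    specs <- lapply(freqs[seq_len(n)], function(f)
      oscillator_spec(a = 0.98, f_hz = f, fs = 100, sigma2 = 3))
    model <- build_nested_oscillator_models(specs, R = matrix(1))
    purrr::map(seq_len(reps), function(i) {
      sim <- simulate_nested_oscillators(model, specs, 1000L,
                                         seed = rep_seeds[i] + n)
      acc <- run_inference_methods(model, sim, methods, n_fp = 50L,
                                   center = FALSE)
      tibble::tibble(rep = i, n_osc = n, method = names(acc),
                     accuracy = unname(acc))
    }) |> dplyr::bind_rows()
  })
}
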