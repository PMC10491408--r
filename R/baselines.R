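#' Static multiple-model switching inference
#'
#' The classical static multiple-model estimator: a bank of `M` independent
#' Kalman filters, each conditioning on the whole past under its own
#' candidate's dynamics, with model probabilities updated recursively by
#' Bayes' rule on the one-step predictive densities. "Static" refers to the
#' model hypothesis: no transition dynamics are placed on the switch state
#' (the filters never exchange state estimates and the Markov chain is
#' ignored). As is standard for this estimator, the probabilities are kept
#' above a small floor (`p_floor`) so that the bank remains adaptive when a
#' candidate's posterior weight collapses.
#'
#' @param model A `switching_model`.
#' @param y Observations.
#' @param p_floor Lower bound on per-step model probabilities.
#' @return Object of class `baseline_posterior` with `probs` (`T x M`, rows
#'   sum to 1) and `labels` (0.5-threshold / argmax path).
#' @export
static_switching <- function(model, y, p_floor = 0.01) {
  y <- as_observations(y)
  M <- model$M; T_ <- nrow(y)
  ll <- vapply(model$ssms,
               function(s) kalman_filter(s, y, model$R)$ll,
               numeric(T_))
  ll <- rbind(ll)
  w <- model$chain$rho
  probs <- matrix(0, T_, M)
  for (t in seq_len(T_)) {
    lw <- log(w) + ll[t, ]
    w <- exp(lw - logsumexp(lw))
    w <- pmax(w / sum(w), p_floor)
    w <- w / sum(w)
    probs[t, ] <- w
  }
  baseline_posterior(probs)
}

baseline_posterior <- function(probs) {
  M <- ncol(probs)
  labels <- if (M == 2L) ifelse(probs[, 1] >= 0.5, 1L, 2L)
            else max.col(probs, ties.method = "first")
  structure(list(probs = probs, labels = as.integer(labels)),
            class = "baseline_posterior")
}

# Map every candidate of a nested-block model onto the union state so all
# candidates share one dimension: absent blocks keep their own dynamics but
# are simply unobserved (zero columns of G).
expand_to_union <- function(model) {
  blocks_of <- lapply(model$ssms, function(s) s$blocks)
  if (any(vapply(blocks_of, is.null, logical(1))))
    stop("candidate models differ in state dimension and carry no block ",
         "structure to map them onto a union state")
  labels <- unique(unlist(lapply(blocks_of, function(b)
    vapply(b, function(x) x$label, character(1)))))
  nb <- length(labels)
  d <- 2L * nb
  # union dynamics per block label: taken from any candidate containing it
  ref <- setNames(vector("list", nb), labels)
  for (b in unlist(blocks_of, recursive = FALSE))
    if (is.null(ref[[b$label]])) ref[[b$label]] <- b
  ssms <- vector("list", model$M)
  for (m in seq_len(model$M)) {
    F <- matrix(0, d, d); Q <- matrix(0, d, d); G <- matrix(0, 1, d)
    Q0 <- matrix(0, d, d); mu <- rep(0, d)
    own <- vapply(blocks_of[[m]], function(x) x$label, character(1))
    old <- model$ssms[[m]]
    for (j in seq_len(nb)) {
      idx <- (2L * j - 1L):(2L * j)
      b <- ref[[labels[j]]]
      F[idx, idx] <- b$a * rot_mat(b$omega)
      Q[idx, idx] <- b$sigma2 * diag(2)
      pos <- match(labels[j], own)
      if (!is.na(pos)) {
        oidx <- blocks_of[[m]][[pos]]$idx
        bb <- blocks_of[[m]][[pos]]
        F[idx, idx] <- bb$a * rot_mat(bb$omega)
        Q[idx, idx] <- bb$sigma2 * diag(2)
        G[1, idx] <- old$G[1, oidx]
        Q0[idx, idx] <- old$Q0[oidx, oidx]
        mu[idx] <- old$mu[oidx]
      } else {
        Q0[idx, idx] <- b$sigma2 / max(1 - b$a^2, 1e-3) * diag(2)
      }
    }
    ssms[[m]] <- gaussian_ssm(mu, Q0, F, Q, G, fs = old$fs)
  }
  switching_model(ssms, model$chain, model$R)
}

#' Interacting multiple models (IMM) filter
#'
#' The classical Gaussian-merging approximation: at each step, per-candidate
#' states are mixed according to the transition matrix, filtered through each
#' candidate's dynamics, re-weighted by their predictive likelihoods, and the
#' model probabilities updated. Candidates must share one state dimension;
#' nested oscillator candidates are mapped onto the union state first (absent
#' blocks evolve unobserved).
#'
#' @inheritParams static_switching
#' @return A `baseline_posterior` of filtered model probabilities.
#' @export
imm <- function(model, y) {
  y <- as_observations(y)
  dims <- vapply(model$ssms, state_dim, 1L)
  if (length(unique(dims)) > 1L) model <- expand_to_union(model)
  M <- model$M; T_ <- nrow(y); p <- model$p
  d <- state_dim(model$ssms[[1]])
  phi <- model$chain$phi
  R <- model$R

  mu_prob <- model$chain$rho
  xs <- lapply(model$ssms, function(s) s$mu)
  Ps <- lapply(model$ssms, function(s) s$Q0)
  probs <- matrix(0, T_, M)

  for (t in seq_len(T_)) {
    # mixing
    pred_prob <- as.numeric(phi %*% mu_prob)
    pred_prob <- pred_prob / sum(pred_prob)
    x0 <- vector("list", M); P0 <- vector("list", M)
    for (m in seq_len(M)) {
      w <- phi[m, ] * mu_prob
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / M, M)
      xm <- Reduce(`+`, Map(`*`, xs, w))
      Pm <- matrix(0, d, d)
      for (n in seq_len(M)) {
        dv <- xs[[n]] - xm
        Pm <- Pm + w[n] * (Ps[[n]] + tcrossprod(dv))
      }
      x0[[m]] <- xm; P0[[m]] <- 0.5 * (Pm + t(Pm))
    }
    # per-model filtering
    lls <- numeric(M)
    for (m in seq_len(M)) {
      s <- model$ssms[[m]]
      xp <- s$F %*% x0[[m]]
      Pp <- s$F %*% P0[[m]] %*% t(s$F) + s$Q
      S <- s$G %*% Pp %*% t(s$G) + R
      Si <- solve(S)
      innov <- y[t, ] - as.numeric(s$G %*% xp)
      K <- Pp %*% t(s$G) %*% Si
      xs[[m]] <- as.numeric(xp + K %*% innov)
      IKG <- diag(d) - K %*% s$G
      Ps[[m]] <- 0.5 * ((IKG %*% Pp %*% t(IKG) + K %*% R %*% t(K)) +
                        t(IKG %*% Pp %*% t(IKG) + K %*% R %*% t(K)))
      lls[m] <- -0.5 * (p * log(2 * pi) +
                        as.numeric(determinant(S, log = TRUE)$modulus) +
                        sum(innov * (Si %*% innov)))
    }
    lw <- log(pred_prob) + lls
    mu_prob <- exp(lw - logsumexp(lw))
    mu_prob <- mu_prob / sum(mu_prob)
    probs[t, ] <- mu_prob
  }
  baseline_posterior(probs)
}

#' Observation-switching Gaussian merging (Shumway-Stoffer 1991 style)
#'
#' For candidate sets that share one set of dynamics and differ only in the
#' observation matrix, runs a single filtered state with
#' probability-weighted measurement updates: at each step the per-candidate
#' innovations yield likelihood weights against the prior `rho`, the state
#' update is the weighted mixture of candidate updates, and the weights are
#' reported as filtered model probabilities.
#'
#' @inheritParams static_switching
#' @return A `baseline_posterior`.
#' @export
shumway_stoffer_merge <- function(model, y) {
  y <- as_observations(y)
  dims <- vapply(model$ssms, state_dim, 1L)
  if (length(unique(dims)) > 1L) model <- expand_to_union(model)
  same_dyn <- all(vapply(model$ssms[-1], function(s)
    isTRUE(all.equal(s$F, model$ssms[[1]]$F)) &&
    isTRUE(all.equal(s$Q, model$ssms[[1]]$Q)), logical(1)))
  if (!same_dyn)
    stop("this merging method requires candidates sharing (F, Q); ",
         "only the observation matrix may switch")
  s1 <- model$ssms[[1]]
  d <- state_dim(s1); p <- model$p
  M <- model$M; T_ <- nrow(y)
  R <- model$R; rho <- model$chain$rho

  x <- s1$mu; P <- s1$Q0
  probs <- matrix(0, T_, M)
  for (t in seq_len(T_)) {
    xp <- s1$F %*% x
    Pp <- s1$F %*% P %*% t(s1$F) + s1$Q
    lls <- numeric(M)
    xu <- vector("list", M); Pu <- vector("list", M)
    for (m in seq_len(M)) {
      G <- model$ssms[[m]]$G
      S <- G %*% Pp %*% t(G) + R
      Si <- solve(S)
      innov <- y[t, ] - as.numeric(G %*% xp)
      K <- Pp %*% t(G) %*% Si
      xu[[m]] <- as.numeric(xp + K %*% innov)
      IKG <- diag(d) - K %*% G
      Pu[[m]] <- IKG %*% Pp %*% t(IKG) + K %*% R %*% t(K)
      lls[m] <- -0.5 * (p * log(2 * pi) +
                        as.numeric(determinant(S, log = TRUE)$modulus) +
                        sum(innov * (Si %*% innov)))
    }
    lw <- log(rho) + lls
    w <- exp(lw - logsumexp(lw)); w <- w / sum(w)
    x <- Reduce(`+`, Map(`*`, xu, w))
    P <- matrix(0, d, d)
    for (m in seq_len(M)) {
      dv <- xu[[m]] - x
      P <- P + w[m] * (Pu[[m]] + tcrossprod(dv))
    }
    P <- 0.5 * (P + t(P))
    probs[t, ] <- w
  }
  baseline_posterior(probs)
}

#' Random segmentation baseline
#'
#' Independent uniform labels over the `M` candidates, the chance floor for
#' segmentation accuracy comparisons.
#'
#' @param T_len Number of time points.
#' @param M Number of candidate models.
#' @param seed Optional seed.
#' @return Integer labels of length `T_len`.
#' @export
random_segmentation <- function(T_len, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (M == 1L) return(rep(1L, T_len))
  sample.int(M, T_len, replace = TRUE)
}
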