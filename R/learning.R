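#' EM configuration
#'
#' Controls the outer generalized-EM loop and which parameter blocks the
#' M-step updates. `G` updates default to off: observation matrices are
#' structural (they define what each candidate observes) and are normally
#' held fixed.
#'
#' @param max_em_iter Maximum EM iterations.
#' @param f_rel_tol Relative free-energy change declaring convergence.
#' @param update Named logical vector choosing which blocks to update among
#'   `mu`, `Q0`, `F`, `Q`, `G`, `R`, `rho`, `phi`.
#' @param priors Optional MAP prior specification from [map_priors()]
#'   (oscillator-structured models only).
#' @return An `em_config` list.
#' @export
em_config <- function(max_em_iter = 50L, f_rel_tol = 1e-5,
                      update = c(mu = TRUE, Q0 = TRUE, F = TRUE, Q = TRUE,
                                 G = FALSE, R = TRUE, rho = TRUE, phi = TRUE),
                      priors = NULL) {
  stopifnot(max_em_iter >= 1L)
  flags <- c(mu = TRUE, Q0 = TRUE, F = TRUE, Q = TRUE, G = FALSE, R = TRUE,
             rho = TRUE, phi = TRUE)
  flags[names(update)] <- update
  structure(list(max_em_iter = as.integer(max_em_iter),
                 f_rel_tol = f_rel_tol, update = flags, priors = priors),
            class = "em_config")
}

#' MAP priors for oscillator parameters
#'
#' Weakly-informative priors used in the spindle application: inverse-gamma
#' priors on the state-noise variance `sigma2` and observation-noise variance
#' `R`, and a Gaussian prior on the rotation frequency `omega` centered at
#' its initialization.
#'
#' @param sigma2_shape,sigma2_rate Inverse-gamma hyperparameters for each
#'   block's `sigma2`.
#' @param r_shape,r_rate Inverse-gamma hyperparameters for `R`.
#' @param omega_sd_hz Standard deviation (Hz) of the Gaussian prior on each
#'   block's frequency; the prior mean is the frequency at initialization.
#' @param a_min Lower bound on the damping factor of oscillator blocks.
#'   A positive bound keeps a block narrowband (oscillatory) instead of
#'   letting it degenerate into a broadband noise absorber when its target
#'   rhythm is absent from the data.
#' @return A `map_priors` list.
#' @export
map_priors <- function(sigma2_shape = 0.01, sigma2_rate = 0.01,
                       r_shape = 0.01, r_rate = 0.01, omega_sd_hz = 1,
                       a_min = 0) {
  structure(list(sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 r_shape = r_shape, r_rate = r_rate,
                 omega_sd_hz = omega_sd_hz, a_min = a_min),
            class = "map_priors")
}

#' Sufficient statistics for the M-step
#'
#' Per candidate `m`, accumulates the second-moment sums
#' `A = sum_t E[x_{t-1} x_{t-1}']`, `B = sum_t E[x_t x_{t-1}']`,
#' `C = sum_t E[x_t x_t']` from the smoothed moments (including lag-one
#' cross covariances), the h-weighted observation statistics feeding the `G`
#' and `R` updates, the initial-state moments, and the chain statistics
#' (`p0`, summed pairwise transition posteriors).
#'
#' @param smoothers List of `rts_result`, one per candidate.
#' @param markov_post A `markov_posterior` for the same pass.
#' @param y Observations.
#' @return Object of class `suff_stats`.
#' @export
collect_stats <- function(smoothers, markov_post, y) {
  y <- as_observations(y)
  T_ <- nrow(y)
  M <- length(smoothers)
  h <- markov_post$h
  per_model <- vector("list", M)
  for (m in seq_len(M)) {
    sm <- smoothers[[m]]
    d <- nrow(sm$x_sm)
    x0 <- sm$x_sm[, 1:T_, drop = FALSE]        # x_{t-1}, t = 1..T
    x1 <- sm$x_sm[, 2:(T_ + 1), drop = FALSE]  # x_t
    Psum0 <- apply(sm$P_sm[, , 1:T_, drop = FALSE], c(1, 2), sum)
    Psum1 <- apply(sm$P_sm[, , 2:(T_ + 1), drop = FALSE], c(1, 2), sum)
    Plag <- apply(sm$P_lag, c(1, 2), sum)
    A <- Psum0 + tcrossprod(x0)
    B <- Plag + tcrossprod(x1, x0)
    C <- Psum1 + tcrossprod(x1)
    hm <- h[, m]
    Syy <- crossprod(y * hm, y)                       # p x p
    Syx <- crossprod(y * hm, t(x1))                   # p x d
    dd <- d * d
    Pw <- matrix(sm$P_sm[, , 2:(T_ + 1), drop = FALSE], dd, T_)
    Sxx <- matrix(Pw %*% hm, d, d) + crossprod(t(x1) * sqrt(hm))
    per_model[[m]] <- list(
      A = A, B = B, C = C, Syy = Syy, Syx = Syx, Sxx = Sxx,
      h_sum = sum(hm), x0 = sm$x_sm[, 1], P0 = sm$P_sm[, , 1])
  }
  structure(list(per_model = per_model, h = h, p0 = markov_post$p0,
                 pair_sum = apply(markov_post$pairwise, c(1, 2), sum),
                 T_len = T_),
            class = "suff_stats")
}

obs_outer_sum <- function(pm, G) {
  # sum_t h_t Omega_t for one model given an observation matrix G
  pm$Syy - G %*% t(pm$Syx) - pm$Syx %*% t(G) + G %*% pm$Sxx %*% t(G)
}

#' Expected complete-data log-likelihood
#'
#' Evaluates the expectation of the complete log-likelihood under the
#' variational posterior, as a function of the model parameters at fixed
#' sufficient statistics. The M-step maximizes this quantity; tests use it to
#' verify that updates never decrease it.
#'
#' @param model A `switching_model`.
#' @param stats A `suff_stats`.
#' @return Scalar.
#' @export
expected_cll <- function(model, stats) {
  T_ <- stats$T_len; p <- model$p
  Ri <- solve(model$R)
  ldR <- p * log(2 * pi) + as.numeric(determinant(model$R, log = TRUE)$modulus)
  total <- -T_ / 2 * ldR
  for (m in seq_len(model$M)) {
    ssm <- model$ssms[[m]]; pm <- stats$per_model[[m]]
    d <- state_dim(ssm)
    total <- total - 0.5 * sum(Ri * obs_outer_sum(pm, ssm$G))
    ldQ0 <- d * log(2 * pi) + as.numeric(determinant(ssm$Q0, log = TRUE)$modulus)
    dev0 <- pm$x0 - ssm$mu
    total <- total - 0.5 * ldQ0 -
      0.5 * sum(solve(ssm$Q0) * (tcrossprod(dev0) + pm$P0))
    ldQ <- d * log(2 * pi) + as.numeric(determinant(ssm$Q, log = TRUE)$modulus)
    S <- pm$C - pm$B %*% t(ssm$F) - ssm$F %*% t(pm$B) +
      ssm$F %*% pm$A %*% t(ssm$F)
    total <- total - T_ / 2 * ldQ - 0.5 * sum(solve(ssm$Q) * S)
  }
  rho <- model$chain$rho; phi <- model$chain$phi
  total <- total + sum(ifelse(stats$p0 > 0, stats$p0 * log(rho), 0)) +
    sum(ifelse(stats$pair_sum > 0, stats$pair_sum * log(phi), 0))
  total
}

#' M-step: closed-form parameter updates
#'
#' Updates the switching-model parameters from sufficient statistics:
#' initial moments `mu`, `Q0`; dynamics `F = B A^{-1}` and `Q`; optionally
#' the observation matrices `G`; the chain `rho` and column-normalized `phi`;
#' and the shared observation noise `R`, which pools the h-weighted
#' observation outer products across candidates. Tied parameter groups pool
#' their statistics before solving: element-tied `F` is solved by the pooled
#' normal equations restricted to the free elements, tied `Q` groups average
#' their residual moments, and shared oscillator blocks sum their block
#' statistics before the structured `(a, omega, sigma2)` update.
#'
#' @param model A `switching_model`.
#' @param stats A `suff_stats` from [collect_stats()].
#' @param cfg An [em_config()].
#' @return The updated `switching_model`.
#' @export
mstep <- function(model, stats, cfg = em_config()) {
  up <- cfg$update
  M <- model$M; T_ <- stats$T_len
  ssms <- model$ssms
  tying <- model$tying
  oscillator <- !is.null(ssms[[1]]$blocks)

  for (m in seq_len(M)) {
    pm <- stats$per_model[[m]]
    if (up[["mu"]]) ssms[[m]]$mu <- as.numeric(pm$x0)
    if (up[["Q0"]]) {
      dev <- pm$x0 - ssms[[m]]$mu
      ssms[[m]]$Q0 <- 0.5 * (pm$P0 + tcrossprod(dev) +
                             t(pm$P0 + tcrossprod(dev)))
    }
  }

  if (oscillator) {
    if (up[["F"]] || up[["Q"]])
      ssms <- mstep_oscillator(ssms, stats, tying, T_, cfg$priors)
  } else {
    if (up[["F"]]) {
      if (!is.null(tying) && !is.null(tying$F_ids)) {
        ssms <- mstep_tied_F(ssms, stats, tying$F_ids)
      } else {
        for (m in seq_len(M)) {
          pm <- stats$per_model[[m]]
          Fm <- tryCatch(t(solve(pm$A, t(pm$B))), error = function(e)
            stop("singular A statistic in F update for model ", m))
          ssms[[m]]$F <- Fm
        }
      }
    }
    if (up[["Q"]]) {
      groups <- if (!is.null(tying) && !is.null(tying$Q_groups))
        tying$Q_groups else as.list(seq_len(M))
      for (grp in groups) {
        S <- 0
        for (m in grp) {
          pm <- stats$per_model[[m]]; Fm <- ssms[[m]]$F
          S <- S + pm$C - pm$B %*% t(Fm) - Fm %*% t(pm$B) +
            Fm %*% pm$A %*% t(Fm)
        }
        Qnew <- 0.5 * (S + t(S)) / (T_ * length(grp))
        for (m in grp) ssms[[m]]$Q <- Qnew
      }
    }
  }

  if (up[["G"]]) {
    for (m in seq_len(M)) {
      pm <- stats$per_model[[m]]
      ssms[[m]]$G <- pm$Syx %*% solve(pm$Sxx)
    }
  }

  R <- model$R
  if (up[["R"]]) {
    W <- 0
    for (m in seq_len(M)) W <- W + obs_outer_sum(stats$per_model[[m]], ssms[[m]]$G)
    R <- 0.5 * (W + t(W)) / T_
    if (!is.null(cfg$priors)) {
      pr <- cfg$priors; p <- model$p
      # isotropic inverse-gamma shrinkage on the diagonal scale
      R <- (W + 2 * pr$r_rate * diag(p)) / (T_ + 2 * (pr$r_shape + 1))
      R <- 0.5 * (R + t(R))
    }
  }

  chain <- model$chain
  if (up[["rho"]]) chain$rho <- pmax(stats$p0, 0) / sum(pmax(stats$p0, 0))
  if (up[["phi"]]) {
    phi <- stats$pair_sum
    cs <- colSums(phi)
    cs[cs == 0] <- 1
    chain$phi <- sweep(phi, 2, cs, "/")
  }
  model$ssms <- ssms
  model$chain <- markov_chain(chain$rho, chain$phi)
  model$R <- R
  model
}

# pooled normal equations for element-masked / cross-model shared F.
# vec(F_m) = S_m theta + fixed, with sum_m S_m' (A_m kron Qinv_m) S_m theta
#           = sum_m S_m' [vec(Qinv_m B_m) - (A_m kron Qinv_m) fixed_m]
mstep_tied_F <- function(ssms, stats, F_ids) {
  M <- length(ssms)
  ids <- unique(stats::na.omit(unlist(F_ids)))
  k <- length(ids)
  lhs <- matrix(0, k, k); rhs <- numeric(k)
  sel <- function(idm) {
    Sm <- matrix(0, length(idm), k)
    for (j in seq_along(ids)) Sm[which(!is.na(idm) & idm == ids[j]), j] <- 1
    Sm
  }
  for (m in seq_len(M)) {
    pm <- stats$per_model[[m]]
    Qi <- solve(ssms[[m]]$Q)
    K <- kronecker(pm$A, Qi)  # for vec(F): d/dvecF of Tr{Qi F A F'} = 2 (A kron Qi) vecF
    idm <- as.vector(F_ids[[m]])
    Sm <- sel(idm)
    fixed <- as.vector(ssms[[m]]$F)
    fixed[!is.na(idm)] <- 0
    lhs <- lhs + t(Sm) %*% K %*% Sm
    rhs <- rhs + as.numeric(t(Sm) %*% (as.vector(Qi %*% pm$B) - K %*% fixed))
  }
  # fully-free unshared models keep the closed form (bitwise match to untied)
  free_solo <- vapply(seq_len(M), function(m) {
    idm <- as.vector(F_ids[[m]])
    all(!is.na(idm)) && !any(idm %in% unlist(lapply(F_ids[-m], identity)))
  }, logical(1))
  theta <- solve(lhs, rhs)
  for (m in seq_len(M)) {
    if (free_solo[m]) {
      pm <- stats$per_model[[m]]
      ssms[[m]]$F <- t(solve(pm$A, t(pm$B)))
    } else {
      idm <- as.vector(F_ids[[m]])
      Fv <- as.vector(ssms[[m]]$F)
      for (j in seq_along(ids)) Fv[which(!is.na(idm) & idm == ids[j])] <- theta[j]
      ssms[[m]]$F <- matrix(Fv, nrow(ssms[[m]]$F))
    }
  }
  ssms
}

# structured update for oscillator blocks: F = a R(omega), Q = sigma2 I2,
# with blocks pooled across candidates when tied by label.
mstep_oscillator <- function(ssms, stats, tying, T_, priors = NULL) {
  M <- length(ssms)
  shared <- if (!is.null(tying)) tying$share_blocks else character(0)
  # gather block occurrences: label -> list of (model, idx)
  occ <- list()
  for (m in seq_len(M)) {
    for (b in ssms[[m]]$blocks) {
      key <- if (b$label %in% shared) b$label else sprintf("%s@%d", b$label, m)
      occ[[key]] <- c(occ[[key]], list(list(m = m, b = b)))
    }
  }
  for (key in names(occ)) {
    tr_c <- 0; tr_s <- 0; trA <- 0; trC <- 0
    for (o in occ[[key]]) {
      pm <- stats$per_model[[o$m]]; idx <- o$b$idx
      Ab <- pm$A[idx, idx]; Bb <- pm$B[idx, idx]; Cb <- pm$C[idx, idx]
      tr_c <- tr_c + Bb[1, 1] + Bb[2, 2]
      tr_s <- tr_s + Bb[2, 1] - Bb[1, 2]
      trA <- trA + Ab[1, 1] + Ab[2, 2]
      trC <- trC + Cb[1, 1] + Cb[2, 2]
    }
    n_occ <- length(occ[[key]])
    omega <- atan2(tr_s, tr_c)
    if (!is.null(priors)) {
      fs <- ssms[[1]]$fs %||% 1
      o0 <- occ[[key]][[1]]$b$omega0 %||% occ[[key]][[1]]$b$omega
      kap <- 2 * pi * priors$omega_sd_hz / fs
      amp <- sqrt(tr_c^2 + tr_s^2)
      obj <- function(w) amp * cos(w - omega) / occ[[key]][[1]]$b$sigma2 -
        (w - o0)^2 / (2 * kap^2)
      omega <- stats::optimize(obj, interval = omega + c(-1, 1) * pi / 2,
                               maximum = TRUE)$maximum
    }
    a <- (tr_c * cos(omega) + tr_s * sin(omega)) / trA
    a_lo <- if (!is.null(priors)) max(priors$a_min, 1e-6) else 1e-6
    a <- min(max(a, a_lo), 1)
    resid <- trC - 2 * a * (tr_c * cos(omega) + tr_s * sin(omega)) + a^2 * trA
    denom <- 2 * T_ * n_occ
    sigma2 <- if (!is.null(priors))
      (resid / 2 + priors$sigma2_rate) / (denom / 2 + priors$sigma2_shape + 1)
    else resid / denom
    sigma2 <- max(sigma2, 1e-12)
    for (o in occ[[key]]) {
      m <- o$m; idx <- o$b$idx
      ssms[[m]]$F[idx, idx] <- a * rot_mat(omega)
      ssms[[m]]$Q[idx, idx] <- sigma2 * diag(2)
      for (j in seq_along(ssms[[m]]$blocks)) {
        if (identical(ssms[[m]]$blocks[[j]]$idx, idx)) {
          ssms[[m]]$blocks[[j]]$a <- a
          ssms[[m]]$blocks[[j]]$omega <- omega
          ssms[[m]]$blocks[[j]]$sigma2 <- sigma2
        }
      }
    }
  }
  ssms
}

#' Variational Bayesian EM for switching state-space models
#'
#' Alternates the structured variational E-step ([fixed_point_estep()]) with
#' closed-form M-steps ([mstep()]) until the negative free energy stabilizes.
#' With interpolated initialization the evidence is recomputed from
#' interpolated densities under the current parameters at every E-step; with
#' annealed initialization the temperature schedule is applied at every
#' E-step but the responsibilities warm-start from the previous E-step after
#' the first.
#'
#' @param model Initial `switching_model`.
#' @param y Observations.
#' @param ecfg An [estep_config()].
#' @param mcfg An [em_config()].
#' @param anneal Optional temperature schedule for annealed E-steps.
#' @return Object of class `vbem_fit`: `model` (fitted), `estep` (final
#'   `vb_estep`), `f_trace` (free energy per EM iteration), `n_iter`,
#'   `converged`.
#' @export
vbem <- function(model, y, ecfg = estep_config(), mcfg = em_config(),
                 anneal = NULL) {
  y <- as_observations(y)
  f_trace <- numeric(0)
  est <- NULL
  converged <- FALSE
  warm_h <- NULL
  for (i in seq_len(mcfg$max_em_iter)) {
    est <- if (ecfg$init_mode == "annealed" && !is.null(warm_h)) {
      fixed_point_estep(model, y, ecfg, anneal = anneal, h_init = warm_h)
    } else {
      fixed_point_estep(model, y, ecfg, anneal = anneal)
    }
    if (ecfg$init_mode == "annealed") warm_h <- est$h
    f_cur <- est$free_energy
    if (length(f_trace) && is.finite(f_cur) &&
        f_cur < f_trace[length(f_trace)] - 100 * mcfg$f_rel_tol * max(1, abs(f_cur))) {
      # generalized EM with re-initialized E-steps need not be monotone
      warning("free energy decreased at EM iteration ", i, call. = FALSE)
    }
    if (length(f_trace) && is.finite(f_cur)) {
      rel <- abs(f_cur - f_trace[length(f_trace)]) / max(1, abs(f_cur))
      if (rel < mcfg$f_rel_tol) {
        f_trace <- c(f_trace, f_cur)
        converged <- TRUE
        break
      }
    }
    f_trace <- c(f_trace, f_cur)
    stats <- collect_stats(est$smoothers, est$markov, y)
    model <- mstep(model, stats, mcfg)
  }
  structure(list(model = model, estep = est, f_trace = f_trace,
                 n_iter = length(f_trace), converged = converged, y = y),
            class = "vbem_fit")
}

#' @export
print.vbem_fit <- function(x, ...) {
  cat("<vbem_fit>", x$model$M, "candidates;", x$n_iter, "EM iterations",
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  cat("  final free energy:", format(x$f_trace[length(x$f_trace)]), "\n")
  invisible(x)
}

#' Serialize a fitted switching model to JSON
#'
#' Writes all matrices, the chain parameters, and the tying declaration to a
#' structured JSON document readable by [read_model_json()].
#'
#' @param model A `switching_model`.
#' @param path Output file path.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    R = model$R,
    rho = model$chain$rho,
    phi = model$chain$phi,
    ssms = lapply(model$ssms, function(s)
      list(mu = s$mu, Q0 = s$Q0, F = s$F, Q = s$Q, G = s$G, fs = s$fs)),
    tying = if (!is.null(model$tying)) unclass(model$tying) else NULL
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ssms <- lapply(seq_len(length(doc$ssms$mu)), function(i) NULL)
  # jsonlite simplification differs for homogeneous lists; rebuild defensively
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tomat <- function(x) {
    m <- do.call(rbind, lapply(x, function(r) unlist(r)))
    storage.mode(m) <- "double"; m
  }
  ssms <- lapply(raw$ssms, function(s)
    gaussian_ssm(unlist(s$mu), tomat(s$Q0), tomat(s$F), tomat(s$Q), tomat(s$G),
                 fs = s$fs))
  chain <- markov_chain(unlist(raw$rho), tomat(raw$phi))
  switching_model(ssms, chain, tomat(raw$R))
}
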