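# Shared fixtures and independent oracles used across the suite.

random_scalar_ssm <- function(seed) {
  set.seed(seed)
  gaussian_ssm(mu = rnorm(1), Q0 = matrix(runif(1, 0.5, 2)),
               F = matrix(runif(1, -0.95, 0.95)),
               Q = matrix(runif(1, 0.3, 2)),
               G = matrix(runif(1, 0.5, 2)))
}

random_mv_ssm <- function(seed, d = 2, p = 1) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  F <- 0.9 * A / max(abs(eigen(A, only.values = TRUE)$values))
  Qh <- matrix(rnorm(d * d, sd = 0.5), d)
  Q0h <- matrix(rnorm(d * d, sd = 0.7), d)
  gaussian_ssm(mu = rnorm(d), Q0 = crossprod(Q0h) + 0.2 * diag(d),
               F = F, Q = crossprod(Qh) + 0.2 * diag(d),
               G = matrix(rnorm(p * d), p, d))
}

# draw a y sequence jointly from the model via the dense oracle
draw_from_oracle <- function(or, seed) {
  set.seed(seed)
  L <- t(chol(or$cov + 1e-12 * diag(nrow(or$cov))))
  z <- or$mean + L %*% rnorm(nrow(L))
  yi <- unlist(or$y_idx)
  p <- length(or$y_idx[[1]])
  matrix(z[yi], ncol = p, byrow = TRUE)
}

oracle_loglik <- function(or, y) {
  yi <- unlist(or$y_idx)
  S <- or$cov[yi, yi]
  m <- or$mean[yi]
  v <- as.vector(t(y)) - m
  -0.5 * (length(yi) * log(2 * pi) +
          as.numeric(determinant(S, logarithm = TRUE)$modulus) +
          sum(v * solve(S, v)))
}

# conditional moments of the stacked states given all observations
oracle_smoother <- function(or, y) {
  yi <- unlist(or$y_idx)
  xi <- unlist(or$x_idx)
  Sy <- or$cov[yi, yi]
  Sxy <- or$cov[xi, yi]
  v <- as.vector(t(y)) - or$mean[yi]
  list(mean = or$mean[xi] + Sxy %*% solve(Sy, v),
       cov = or$cov[xi, xi] - Sxy %*% solve(Sy, t(Sxy)))
}

# leave-one-out conditional log-density of each observation block
oracle_interpolated <- function(or, y) {
  yv <- as.vector(t(y))
  T_ <- length(or$y_idx)
  vapply(seq_len(T_), function(t) {
    it <- or$y_idx[[t]]
    rest <- setdiff(unlist(or$y_idx), it)
    S11 <- or$cov[it, it, drop = FALSE]
    S12 <- or$cov[it, rest, drop = FALSE]
    S22 <- or$cov[rest, rest]
    yi_all <- unlist(or$y_idx)
    mrest <- or$mean[rest]
    mcond <- or$mean[it] + S12 %*% solve(S22, yv[match(rest, yi_all)] - mrest)
    vcond <- S11 - S12 %*% solve(S22, t(S12))
    r <- yv[match(it, yi_all)] - mcond
    -0.5 * (length(it) * log(2 * pi) +
            as.numeric(determinant(vcond, logarithm = TRUE)$modulus) +
            sum(r * solve(vcond, r)))
  }, numeric(1))
}

# exhaustive path enumeration oracle for the switching chain posterior
enumerate_chain <- function(g, chain) {
  T_ <- nrow(g); M <- chain$M
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), T_ + 1L)))
  lp <- apply(paths, 1, function(s) {
    v <- log(chain$rho[s[1]])
    for (t in seq_len(T_))
      v <- v + log(chain$phi[s[t + 1], s[t]]) + g[t, s[t + 1]]
    v
  })
  logZ <- max(lp) + log(sum(exp(lp - max(lp))))
  w <- exp(lp - logZ)
  h <- vapply(seq_len(M), function(m)
    vapply(seq_len(T_), function(t) sum(w[paths[, t + 1] == m]), numeric(1)),
    numeric(T_))
  pair <- array(0, c(M, M, T_))
  for (t in seq_len(T_))
    for (m in seq_len(M))
      for (n in seq_len(M))
        pair[m, n, t] <- sum(w[paths[, t + 1] == m & paths[, t] == n])
  p0 <- vapply(seq_len(M), function(m) sum(w[paths[, 1] == m]), numeric(1))
  list(logZ = logZ, h = rbind(h), pair = pair, p0 = p0,
       map_path = paths[which.max(lp), -1])
}

# exact switching log-likelihood by enumerating switch paths; each path's
# likelihood factors over candidates with indicator responsibilities
enumerate_switching_loglik <- function(model, y) {
  T_ <- nrow(as_observations(y)); M <- model$M
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), T_ + 1L)))
  lp <- apply(paths, 1, function(s) {
    v <- log(model$chain$rho[s[1]])
    for (t in seq_len(T_)) v <- v + log(model$chain$phi[s[t + 1], s[t]])
    for (m in seq_len(M)) {
      ind <- as.numeric(s[-1] == m)
      v <- v + kalman_filter(model$ssms[[m]], y, model$R, h = ind)$loglik
    }
    v
  })
  max(lp) + log(sum(exp(lp - max(lp))))
}
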