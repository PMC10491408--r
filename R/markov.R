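#' Markov switching-chain parameters
#'
#' Holds the initial state distribution `rho` and the state-transition matrix
#' `phi` of the hidden switching chain. The orientation convention is fixed
#' here once and used everywhere: `phi[m, n]` is the probability of moving
#' *to* state `m` *from* state `n`, so every **column** of `phi` sums to 1.
#' The chain starts at `s_0` (no emission); the first emission happens at
#' `t = 1` after one transition.
#'
#' @param rho Initial state probabilities (length `M`, sums to 1).
#' @param phi `M x M` transition matrix with unit column sums.
#' @return An object of class `markov_chain`.
#' @examples
#' markov_chain(c(0.5, 0.5), phi_diag(2, 0.95))
#' @export
markov_chain <- function(rho, phi) {
  rho <- as.numeric(rho)
  M <- length(rho)
  phi <- as_sq(phi, M, "phi")
  if (any(rho < 0) || abs(sum(rho) - 1) > 1e-8) stop("rho must be a probability vector")
  if (any(phi < 0) || max(abs(colSums(phi) - 1)) > 1e-8)
    stop("columns of phi must sum to 1 (phi[m, n] = P(to m | from n))")
  structure(list(rho = rho, phi = phi, M = M), class = "markov_chain")
}

#' Symmetric sticky transition matrix
#'
#' Convenience builder for an `M x M` transition matrix with `diag_p` on the
#' diagonal and the remaining mass spread evenly off-diagonal.
#'
#' @param M Number of states.
#' @param diag_p Self-transition probability.
#' @export
phi_diag <- function(M, diag_p) {
  if (M == 1L) return(matrix(1, 1, 1))
  off <- (1 - diag_p) / (M - 1)
  phi <- matrix(off, M, M)
  diag(phi) <- diag_p
  phi
}

#' Forward-backward smoothing for the switching chain
#'
#' Hidden-Markov smoothing in the log domain with emission log-weights `g`
#' for `t = 1..T` and an initial state `s_0` that carries no emission.
#' Returns posterior marginals, pairwise transition posteriors, the log
#' messages, and the log-normalizer.
#'
#' @param g `T x M` matrix of emission log-weights (finite, `-Inf` allowed to
#'   veto a state at a time point).
#' @param chain A [markov_chain()].
#' @return An object of class `markov_posterior`: `h` (`T x M` marginals,
#'   rows sum to 1), `p0` (marginal of `s_0`), `pairwise` (`M x M x T`,
#'   slice `t` holding `P(s_t = m, s_{t-1} = n | y)`), `log_alpha`,
#'   `log_beta` (`(T+1) x M`), and `logZ`.
#' @export
forward_backward <- function(g, chain) {
  g <- rbind(g)
  if (ncol(g) != chain$M) stop("g must have M = ", chain$M, " columns")
  if (anyNA(g)) stop("g must not contain NA")
  out <- fb_cpp(g, log(chain$rho), log(chain$phi))
  out$p0 <- drop(out$p0)
  out$chain <- chain
  out$g <- g
  class(out) <- "markov_posterior"
  out
}

#' Most likely switching path
#'
#' Viterbi decoding of the maximum a posteriori joint path under the same
#' emission and initial-state conventions as [forward_backward()].
#'
#' @inheritParams forward_backward
#' @return Integer vector of length `T` with states in `1..M`.
#' @export
viterbi <- function(g, chain) {
  g <- rbind(g)
  if (ncol(g) != chain$M) stop("g must have M = ", chain$M, " columns")
  as.integer(drop(viterbi_cpp(g, log(chain$rho), log(chain$phi))))
}

#' Filtered (forward-only) state probabilities
#'
#' Normalizes the forward messages of a [forward_backward()] result, giving
#' `P(s_t = m | y_{1:t})` for `t = 1..T`. At `t = T` these agree with the
#' smoothed marginals.
#'
#' @param post A `markov_posterior`.
#' @return `T x M` matrix of filtered probabilities.
#' @export
filtered_probs <- function(post) {
  stopifnot(inherits(post, "markov_posterior"))
  la <- post$log_alpha[-1, , drop = FALSE]
  sweep_exp <- exp(la - apply(la, 1, logsumexp))
  sweep_exp / rowSums(sweep_exp)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}
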