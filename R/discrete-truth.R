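#' Discrete ground-truth Markov system
#'
#' Builds a reversible, row-stochastic transition matrix with a planted
#' metastable block structure plus random per-ensemble bias energies.  The
#' matrix is constructed from a symmetric positive weight matrix (large
#' within blocks, small between neighbouring blocks), which guarantees
#' detailed balance with respect to `pi_true` = row sums of the weights.
#'
#' @param n_states number of states (>= 2).
#' @param n_ensembles number of thermodynamic ensembles; ensemble 1 is
#'   unbiased (zero bias energies).
#' @param seed random seed.
#' @param n_blocks number of metastable blocks (default: 1 for n < 6,
#'   else 3, capped by `n_states`).
#' @param coupling ratio of inter- to intra-block weights; small values give
#'   strong metastability.
#' @param bias_scale standard deviation of the random state bias energies
#'   (kT) for the biased ensembles.
#' @return An object of class `discrete_truth` with elements `n_states`,
#'   `T_true`, `pi_true`, `bias_energies` (n_ensembles x n_states, first row
#'   zero) and `blocks` (planted block labels).
#' @export
generate_discrete_truth <- function(n_states, n_ensembles = 1, seed = 1L,
                                    n_blocks = NULL, coupling = 0.01,
                                    bias_scale = 1.5) {
  if (n_states < 2) stop("n_states must be >= 2")
  set.seed(seed)
  if (is.null(n_blocks)) n_blocks <- if (n_states < 6) 1L else 3L
  n_blocks <- min(n_blocks, n_states)
  blocks <- sort(rep_len(seq_len(n_blocks), n_states))
  W <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) for (j in i:n_states) {
    w <- if (blocks[i] == blocks[j]) runif(1, 0.5, 1) else
      coupling * runif(1, 0.5, 1)
    W[i, j] <- W[j, i] <- w
  }
  diag(W) <- diag(W) + runif(n_states, 0.5, 1.5)  # metastable self-weight
  T_true <- W / rowSums(W)
  pi_true <- rowSums(W) / sum(W)
  bias <- matrix(0, n_ensembles, n_states)
  if (n_ensembles > 1)
    bias[-1, ] <- rnorm((n_ensembles - 1) * n_states, sd = bias_scale)
  structure(list(n_states = n_states, T_true = T_true, pi_true = pi_true,
                 bias_energies = bias, blocks = blocks),
            class = "discrete_truth")
}

#' Biased transition matrix of a discrete truth
#'
#' The chain sampled in ensemble `k` is the Metropolis reweighting of the
#' unbiased chain by the state bias energies: off-diagonal moves are
#' accepted with probability `min(1, exp(-(b_j - b_i)))`, which preserves
#' detailed balance with respect to `pi_true * exp(-b)`.
#'
#' @param truth a [generate_discrete_truth()] object.
#' @param ensemble ensemble index (1 = unbiased).
#' @return row-stochastic matrix.
#' @export
biased_transition_matrix <- function(truth, ensemble) {
  stopifnot(inherits(truth, "discrete_truth"))
  if (ensemble < 1 || ensemble > nrow(truth$bias_energies))
    stop("ensemble index out of range")
  b <- truth$bias_energies[ensemble, ]
  Tb <- truth$T_true * pmin(1, exp(-outer(b, b, function(bi, bj) bj - bi)))
  diag(Tb) <- 0
  diag(Tb) <- 1 - rowSums(Tb)
  Tb
}

#' Sample a discrete trajectory from a truth system
#'
#' @param truth a [generate_discrete_truth()] object.
#' @param ensemble ensemble index; biased ensembles use the Metropolis
#'   reweighted chain of [biased_transition_matrix()].
#' @param n_steps trajectory length in frames (including the start frame).
#' @param seed random seed.
#' @param start starting state (default: drawn from the ensemble's
#'   stationary distribution).
#' @return integer vector of states.
#' @export
sample_chain <- function(truth, ensemble, n_steps, seed = 1L, start = NULL) {
  stopifnot(inherits(truth, "discrete_truth"))
  Tb <- biased_transition_matrix(truth, ensemble)
  set.seed(seed)
  n <- truth$n_states
  if (is.null(start)) {
    pib <- truth$pi_true * exp(-truth$bias_energies[ensemble, ])
    start <- sample.int(n, 1, prob = pib / sum(pib))
  }
  out <- integer(n_steps)
  out[1] <- start
  if (n_steps == 1) return(out)
  cum <- t(apply(Tb, 1, cumsum))
  u <- runif(n_steps - 1)
  for (t in 2:n_steps) {
    out[t] <- findInterval(u[t - 1], cum[out[t - 1], ]) + 1L
  }
  out
}
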