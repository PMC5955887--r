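#' Reversible maximum-likelihood Markov state model
#'
#' Estimates the transition matrix maximizing the likelihood
#' \eqn{\prod_{ij} T_{ij}^{c_{ij}}} under the detailed-balance constraint,
#' by the standard self-consistent iteration on the unnormalized flux matrix
#' \eqn{x_{ij} = (c_{ij}+c_{ji}) / (c_i/x_i + c_j/x_j)}.  Estimation is
#' restricted to the largest connected set of the count-matrix support
#' (undirected, counts > 0); dropped states are reported in the result.
#'
#' @param counts square count matrix (see [count_transitions()]).
#' @param tol convergence threshold on the relative log-likelihood change.
#' @param param_tol additional threshold on the largest change of any
#'   transition probability between sweeps; both must be met.
#' @param maxiter iteration cap.
#' @return An object of class `msm`: `T` (row-stochastic), `pi` (stationary
#'   distribution), `lag` (frames, from the counts attribute if present),
#'   `active` (indices of retained states in the original numbering),
#'   `counts` (restricted counts), `dropped` (removed states).
#' @export
mle_reversible <- function(counts, tol = 1e-10, param_tol = 1e-12,
                           maxiter = 100000L) {
  C <- unclass(as.matrix(counts))
  if (sum(C) == 0) stop("empty count matrix")
  lag <- attr(counts, "lag")
  act <- largest_connected_set(C)
  dropped <- setdiff(seq_len(nrow(C)), act)
  C <- C[act, act, drop = FALSE]
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  ll_old <- -Inf
  T_old <- x / rowSums(x)
  for (it in seq_len(maxiter)) {
    xi <- rowSums(x)
    x <- Csym / outer(ci / xi, ci / xi, "+")
    Tm <- x / rowSums(x)
    ll <- sum(C[C > 0] * log(Tm[C > 0]))
    dT <- max(abs(Tm - T_old))
    T_old <- Tm
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll) &&
        dT <= param_tol) break
    ll_old <- ll
  }
  xi <- rowSums(x)
  structure(list(T = x / xi, pi = xi / sum(xi), lag = lag, active = act,
                 counts = C, dropped = dropped),
            class = "msm")
}

#' Largest connected set of a count matrix
#'
#' @param C count matrix; connectivity is judged on the undirected support
#'   (counts > 0 in either direction).
#' @return integer vector of state indices.
#' @export
largest_connected_set <- function(C) {
  A <- (C + t(C)) > 0
  diag(A) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  which(comp$membership == which.max(comp$csize))
}

#' Stationary distribution of a transition matrix
#'
#' @param T row-stochastic matrix.
#' @return probability vector (left Perron eigenvector, normalized).
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.max(Re(e$values) - 1e3 * abs(Im(e$values)))
  v <- Re(e$vectors[, i])
  v <- v * sign(sum(v))
  if (any(v < -1e-8)) warning("negative entries in the stationary vector")
  v <- pmax(v, 0)
  v / sum(v)
}

# eigenvalues of a reversible T, sorted by modulus (ties: real part),
# computed through the pi-symmetrized matrix for numerical reality
reversible_eigen <- function(T, pi = NULL) {
  if (is.null(pi)) pi <- stationary_distribution(T)
  s <- sqrt(pmax(pi, 1e-300))
  S <- (s * T) / rep(s, each = length(s))  # diag(s) %*% T %*% diag(1/s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(-abs(e$values), -e$values)
  list(values = e$values[ord],
       vectors_right = (1 / s) * e$vectors[, ord, drop = FALSE],
       pi = pi)
}

#' Implied relaxation timescales
#'
#' Computes \eqn{t_i(\tau) = -\tau/\ln \lambda_i(\tau)} for the leading
#' eigenvalues of one or more models estimated at different lag times, and
#' flags non-convergence when the timescales of successive lags differ by
#' more than `rel_tol` (relative).
#'
#' @param models list of `msm` objects (each with its `lag`, in frames), or
#'   a single model.
#' @param n_its number of timescales (excluding the stationary eigenvalue).
#' @param rel_tol relative tolerance used for the convergence flag.
#' @param dt frame duration used to convert lags to time (default 1).
#' @return data frame with columns `lag`, `index`, `timescale` and attribute
#'   `converged` (logical matrix, lags x timescales, comparing each lag with
#'   the previous one).
#' @export
implied_timescales <- function(models, n_its = 3, rel_tol = 0.25, dt = 1) {
  if (inherits(models, "msm")) models <- list(models)
  rows <- lapply(models, function(m) {
    ev <- reversible_eigen(m$T, m$pi)$values
    if (length(ev) < 2) stop("model too small for implied timescales")
    lam <- ev[-1][seq_len(min(n_its, length(ev) - 1))]
    ts <- ifelse(abs(lam) >= 1, Inf,
                 ifelse(lam <= 0, NA_real_, -(m$lag * dt) / log(lam)))
    data.frame(lag = m$lag * dt, index = seq_along(lam) + 1, timescale = ts)
  })
  out <- do.call(rbind, rows)
  lags <- sort(unique(out$lag))
  if (length(lags) >= 2) {
    conv <- sapply(seq_len(n_its), function(k) {
      tsk <- out$timescale[out$index == k + 1][order(out$lag[out$index == k + 1])]
      c(NA, abs(diff(tsk)) <= rel_tol * pmax(abs(head(tsk, -1)), 1e-12))
    })
    attr(out, "converged") <- matrix(conv, nrow = length(lags),
                                     dimnames = list(lags, seq_len(n_its) + 1))
  }
  out
}

#' Bootstrap over whole trajectories
#'
#' Resamples trajectories with replacement, re-runs an estimator on each
#' replicate and summarizes derived scalars by their mean and 5%/95%
#' percentiles.
#'
#' @param trajs list of trajectories (any type the estimator accepts).
#' @param estimator function(list_of_trajs) -> model or scalar(s).
#' @param n_boot number of bootstrap replicates.
#' @param seed random seed.
#' @param statistic optional function(model) -> named numeric vector; if
#'   supplied, a summary table is attached.
#' @return list with `models` (replicate outputs), and if `statistic` was
#'   given, `stats` (replicates x statistics matrix) and `summary`
#'   (mean, q05, q95 per statistic).
#' @export
bootstrap_models <- function(trajs, estimator, n_boot = 10, seed = 1L,
                             statistic = NULL) {
  if (length(trajs) < 2) stop("need at least two trajectories to bootstrap")
  set.seed(seed)
  idx <- replicate(n_boot, sample.int(length(trajs), replace = TRUE),
                   simplify = FALSE)
  models <- lapply(idx, function(i) estimator(trajs[i]))
  out <- list(models = models, indices = idx)
  if (!is.null(statistic)) {
    st <- do.call(rbind, lapply(models, function(m) statistic(m)))
    out$stats <- st
    out$summary <- data.frame(
      statistic = colnames(st) %||% paste0("s", seq_len(ncol(st))),
      mean = colMeans(st),
      q05 = apply(st, 2, quantile, 0.05, names = FALSE),
      q95 = apply(st, 2, quantile, 0.95, names = FALSE))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stationary probability of a collective-variable region
#'
#' Reweights frames by the model's stationary distribution (each frame of
#' microstate i carries weight \eqn{\pi_i / N_i}, the local-equilibrium
#' convention) and sums the weights of frames inside the region.  This
#' resolves structure finer than the discretization, which plain
#' aggregation of microstate probabilities cannot.
#'
#' @param model an `msm` or `tram_model` (uses `pi` over all states).
#' @param disc the matching discretization.
#' @param trajs list of `cv_trajectory` objects (typically the unbiased,
#'   swap-augmented data the model was built from).
#' @param region function(d, alpha1, alpha2) -> logical.
#' @return probability in \[0, 1\].
#' @export
region_probability <- function(model, disc, trajs, region) {
  if (inherits(trajs, "cv_trajectory")) trajs <- list(trajs)
  pi_full <- rep(0, disc$n_states)
  if (length(model$pi) == disc$n_states) pi_full <- model$pi
  else pi_full[model$active] <- model$pi
  states <- lapply(trajs, function(tr) assign_microstates(disc, tr))
  N <- tabulate(unlist(states), nbins = disc$n_states)
  tot <- 0
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    s <- states[[k]]
    inr <- region(tr$d, tr$alpha1, tr$alpha2)
    w <- pi_full[s] / pmax(N[s], 1)
    tot <- tot + sum(w[inr])
  }
  tot
}

#' Chapman-Kolmogorov test
#'
#' Compares the occupation probabilities of state groups predicted by
#' propagating the model, \eqn{T(\tau)^k}, against models re-estimated from
#' the data at lag \eqn{k\tau}.  For each group A the compared quantity is
#' the probability of being in A after \eqn{k\tau} given a start in A
#' distributed according to the stationary distribution restricted to A.
#'
#' @param model an `msm` estimated at lag `model$lag` (frames).
#' @param dtrajs the discrete trajectories the model came from.
#' @param sets list of integer vectors: the state groups (e.g. PCCA sets).
#' @param k_steps multiples of the lag to test (default 1:5).
#' @return data frame with columns `set`, `k`, `predicted`, `estimated`,
#'   `abs_dev`.  Steps without sufficient data are truncated with a warning.
#' @export
ck_test <- function(model, dtrajs, sets, k_steps = 1:5) {
  stopifnot(inherits(model, "msm"))
  n_all <- max(unlist(dtrajs))
  rows <- list()
  for (k in sort(unique(as.integer(k_steps)))) {
    lag_k <- model$lag * k
    if (all(vapply(dtrajs, length, 1L) <= lag_k)) {
      warning("insufficient data at lag multiple k = ", k, "; truncated")
      break
    }
    est <- mle_reversible(count_transitions(dtrajs, lag_k, n_states = n_all))
    Tpow <- matpow(model$T, k)
    for (s in seq_along(sets)) {
      A <- sets[[s]]
      Aact <- match(A, model$active); Aact <- Aact[!is.na(Aact)]
      if (!length(Aact)) next
      w <- model$pi[Aact] / sum(model$pi[Aact])
      pred <- sum(w * rowSums(Tpow[Aact, Aact, drop = FALSE]))
      Aest <- match(A, est$active); Aest <- Aest[!is.na(Aest)]
      w2 <- est$pi[Aest] / sum(est$pi[Aest])
      estv <- sum(w2 * rowSums(est$T[Aest, Aest, drop = FALSE]))
      rows[[length(rows) + 1]] <- data.frame(
        set = s, k = k, predicted = pred, estimated = estv,
        abs_dev = abs(pred - estv))
    }
  }
  do.call(rbind, rows)
}

matpow <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  R
}
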