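#' Reduced bias energies of a trajectory under a set of restraints
#'
#' Evaluates \eqn{U_b/kT} for every frame under every ensemble's bias.
#' The unbiased ensemble (`NULL` spec) contributes a zero column.
#'
#' @param cv_traj a `cv_trajectory` (columns `d`, `alpha1`, `alpha2`).
#' @param specs list of [bias_spec()] objects or `NULL`s, one per ensemble.
#' @param kT thermal energy in the units of the force constants (1 in
#'   reduced units; `0.0083145 * 310` kJ/mol at 310 K).
#' @return numeric matrix, frames x ensembles.
#' @export
evaluate_bias_energies <- function(cv_traj, specs, kT = 1) {
  if (any(!is.finite(cv_traj$d)) || any(!is.finite(cv_traj$alpha1)) ||
      any(!is.finite(cv_traj$alpha2)))
    stop("missing or non-finite collective variables")
  n <- length(cv_traj$d)
  matrix(vapply(specs, function(s)
    bias_energy(s, cv_traj$d, cv_traj$alpha1, cv_traj$alpha2, kT = kT),
    numeric(n)), nrow = n, ncol = length(specs))
}

#' One thermodynamic ensemble of trajectories
#'
#' @param trajs a `cv_trajectory` or list of them, all sampled under `bias`.
#' @param bias a [bias_spec()] or `NULL` for the unbiased ensemble.
#' @param id optional label.
#' @return An object of class `ensemble_data`.
#' @export
ensemble_data <- function(trajs, bias = NULL, id = NULL) {
  if (inherits(trajs, "cv_trajectory") || is.data.frame(trajs))
    trajs <- list(trajs)
  structure(list(trajs = trajs, bias = bias, id = id),
            class = "ensemble_data")
}

#' Multi-ensemble TRAM estimate
#'
#' Combines unbiased and umbrella-biased ensembles into one estimate of the
#' unbiased stationary distribution and reversible transition matrix using
#' the transition-based reweighting analysis method.  Bias energies are
#' evaluated from each frame's collective variables for every ensemble, the
#' frames are pooled per microstate, and the TRAM fixed-point equations are
#' iterated until the largest free-energy change drops below `tol` (kT).
#' With a single unbiased ensemble the result coincides with the reversible
#' maximum-likelihood estimator.
#'
#' @param ensembles list of [ensemble_data()] objects; exactly one must be
#'   unbiased (`bias = NULL`).
#' @param disc a [kmeans_discretize()] discretization used to assign frames.
#' @param lag lag time in frames.
#' @param kT thermal energy for the bias evaluation.
#' @param tol convergence threshold on max |df| per iteration (kT).
#' @param maxiter iteration cap; non-convergence is an error carrying the
#'   convergence history.
#' @param stride keep every `stride`-th frame for the free-energy (frame
#'   weight) part of the estimator; transition counts always use all frames.
#' @return An object of class `tram_model`: `f` (ensembles x microstates
#'   reduced free energies, gauge-fixed so the unbiased weights sum to 1),
#'   `pi` (unbiased stationary distribution over all visited microstates),
#'   `T` (unbiased reversible transition matrix on `active`, the largest
#'   connected set of the unbiased counts), `active`, `history`,
#'   `n_iter`, `lag`.
#' @export
tram_estimate <- function(ensembles, disc, lag, kT = 1, tol = 1e-9,
                          maxiter = 100000L, stride = 1L) {
  specs <- lapply(ensembles, function(e) e$bias)
  unb <- which(vapply(specs, is.null, TRUE))
  if (length(unb) != 1) stop("exactly one unbiased ensemble is required")
  dtrajs <- lapply(ensembles, function(e)
    lapply(e$trajs, function(tr) assign_microstates(disc, tr)))
  cvs <- lapply(ensembles, function(e) e$trajs)
  tram_core(dtrajs, cvs, specs, n_states = disc$n_states, lag = lag,
            kT = kT, tol = tol, maxiter = maxiter, stride = stride,
            unbiased = unb)
}

#' TRAM on pre-discretized data with state-wise bias energies
#'
#' Variant of [tram_estimate()] for systems (such as
#' [generate_discrete_truth()]) where the bias energy is a function of the
#' discrete state only.
#'
#' @param dtrajs_by_ensemble list (one element per ensemble) of lists of
#'   integer state sequences.
#' @param bias_energies matrix (ensembles x states) of reduced energies;
#'   the unbiased ensemble row must be zero.
#' @param lag lag time in frames.
#' @inheritParams tram_estimate
#' @export
tram_discrete <- function(dtrajs_by_ensemble, bias_energies, lag,
                          tol = 1e-9, maxiter = 100000L) {
  unb <- which(apply(bias_energies, 1, function(r) all(r == 0)))
  if (length(unb) < 1) stop("no unbiased (all-zero bias) ensemble found")
  unb <- unb[1]
  n_states <- ncol(bias_energies)
  tram_core(dtrajs_by_ensemble, cvs = NULL, specs = NULL,
            n_states = n_states, lag = lag, kT = 1, tol = tol,
            maxiter = maxiter, stride = 1L, unbiased = unb,
            state_bias = bias_energies)
}

tram_core <- function(dtrajs, cvs, specs, n_states, lag, kT, tol, maxiter,
                      stride, unbiased, state_bias = NULL) {
  K <- length(dtrajs)
  count_mats <- vector("list", K)
  N <- matrix(0L, K, n_states)
  fs_list <- list()
  fb_list <- list()
  for (k in seq_len(K)) {
    count_mats[[k]] <- unclass(count_transitions(dtrajs[[k]], lag,
                                                 n_states = n_states))
    for (ti in seq_along(dtrajs[[k]])) {
      st <- dtrajs[[k]][[ti]]
      keep <- seq(1, length(st), by = stride)
      st_k <- st[keep]
      # strided frames stand in for `stride` frames each, so that the frame
      # and transition parts of the estimator see consistent totals
      N[k, ] <- N[k, ] + stride * tabulate(st_k, nbins = n_states)
      fs_list[[length(fs_list) + 1]] <- st_k
      if (is.null(state_bias))
        fb_list[[length(fb_list) + 1]] <-
          evaluate_bias_energies(cvs[[k]][[ti]][keep, , drop = FALSE],
                                 specs, kT = kT)
    }
  }
  frame_state <- unlist(fs_list)
  if (is.null(state_bias)) {
    frame_bias <- do.call(rbind, fb_list)
    frame_mult <- rep(as.numeric(stride), length(frame_state))
  } else {
    # state-wise biases: collapse frames to one pseudo-frame per visited
    # state with its multiplicity (the estimator only sees sums over X_i)
    mult <- tabulate(frame_state, nbins = n_states)
    frame_state <- which(mult > 0)
    frame_mult <- mult[frame_state]
    frame_bias <- t(state_bias)[frame_state, , drop = FALSE]
  }
  visited <- which(colSums(N) > 0)
  if (length(visited) < n_states) {
    keepmap <- match(seq_len(n_states), visited)
    count_mats <- lapply(count_mats, function(C)
      C[visited, visited, drop = FALSE])
    N <- N[, visited, drop = FALSE]
    frame_state <- keepmap[frame_state]
  }
  n <- length(visited)
  # connectivity across the union of all ensembles' counts
  Cun <- Reduce(`+`, count_mats)
  ccs <- largest_connected_set(Cun)
  if (length(ccs) < n) {
    frags <- setdiff(seq_len(n), ccs)
    stop("state space disconnected across all ensembles; fragments: ",
         paste(visited[frags], collapse = ", "))
  }
  res <- .tram_solve_cpp(lapply(count_mats, function(m) m + 0),
                         matrix(as.integer(N), nrow(N), ncol(N)),
                         frame_state - 1L, frame_bias, frame_mult,
                         as.integer(unbiased - 1L),
                         as.integer(maxiter), tol)
  if (!res$converged)
    stop("TRAM did not converge within ", maxiter,
         " iterations (last max|df| = ",
         signif(tail(res$history, 1), 3), ")")
  f <- res$f
  w <- exp(-f[unbiased, ])
  pi_full <- rep(0, n_states)
  pi_full[visited] <- w / sum(w)
  # unbiased reversible transition matrix on the connected set of the
  # unbiased counts, from the converged f and Lagrange multipliers
  Cu <- count_mats[[unbiased]]
  act_u <- largest_connected_set(Cu)
  Tm <- tram_transition_matrix(Cu[act_u, act_u, drop = FALSE],
                               f[unbiased, act_u],
                               exp(res$log_nu[unbiased, act_u]))
  structure(list(f = f, pi = pi_full, T = Tm,
                 active = visited[act_u], visited = visited,
                 history = res$history, n_iter = res$n_iter,
                 lag = lag, unbiased = unbiased),
            class = "tram_model")
}

tram_transition_matrix <- function(C, f, nu) {
  n <- nrow(C)
  w <- exp(-(f - min(f)))
  Csym <- C + t(C)
  P <- Csym * outer(rep(1, n), w) /
    (outer(nu, w) + t(outer(nu, w)))
  P[Csym == 0] <- 0
  diag(P) <- 0
  rs <- rowSums(P)
  if (any(rs > 1 + 1e-6))
    warning("TRAM transition rows exceed 1 by ", signif(max(rs) - 1, 3),
            "; estimate may not be fully converged")
  diag(P) <- pmax(0, 1 - rs)
  P
}

#' Bootstrap distribution of TRAM models
#'
#' Resamples the unbiased ensemble's trajectories with replacement (biased
#' ensembles are reused unchanged in every replicate) and re-runs
#' [tram_estimate()].
#'
#' @inheritParams tram_estimate
#' @param n_boot number of replicates.
#' @param seed random seed.
#' @param statistic optional function(tram_model) -> named numeric vector.
#' @return list with `models` and, if `statistic` was given, `stats` and a
#'   `summary` table (mean, 5% and 95% percentiles).
#' @export
tram_bootstrap <- function(ensembles, disc, lag, n_boot = 10, seed = 1L,
                           statistic = NULL, ...) {
  specs <- lapply(ensembles, function(e) e$bias)
  unb <- which(vapply(specs, is.null, TRUE))
  if (length(unb) != 1) stop("exactly one unbiased ensemble is required")
  trajs_u <- ensembles[[unb]]$trajs
  set.seed(seed)
  idx <- replicate(n_boot, sample.int(length(trajs_u), replace = TRUE),
                   simplify = FALSE)
  models <- lapply(idx, function(i) {
    ens <- ensembles
    ens[[unb]] <- ensemble_data(trajs_u[i], bias = NULL)
    tram_estimate(ens, disc, lag, ...)
  })
  out <- list(models = models, indices = idx)
  if (!is.null(statistic)) {
    st <- do.call(rbind, lapply(models, statistic))
    out$stats <- st
    out$summary <- data.frame(
      statistic = colnames(st) %||% paste0("s", seq_len(ncol(st))),
      mean = colMeans(st),
      q05 = apply(st, 2, quantile, 0.05, names = FALSE),
      q95 = apply(st, 2, quantile, 0.95, names = FALSE))
  }
  out
}

#' Merge silent unbound microstates before multi-ensemble estimation
#'
#' Microstates belonging to the unbound component that show no transitions
#' in or out of the rest of that component's complement (i.e. no exchange
#' with states outside the component) in the count matrix are re-clustered
#' into a smaller set of centres; all other microstates are untouched.
#'
#' @param disc a [kmeans_discretize()] object.
#' @param counts count matrix at the working lag over `disc`'s states.
#' @param unbound_states microstate indices of the unbound component (from
#'   the preliminary PCCA+ labelling).
#' @param n_new number of merged centres for the qualifying states
#'   (default: one per 7 qualifying states, at least 1).
#' @param seed seed for the merging k-means.
#' @return list with `disc` (reduced discretization), `mapping` (old state
#'   -> new state), `n_merged` (number of qualifying states).
#' @export
resample_unbound <- function(disc, counts, unbound_states,
                             n_new = NULL, seed = 1L) {
  C <- unclass(as.matrix(counts))
  outside <- setdiff(seq_len(disc$n_states), unbound_states)
  qual <- unbound_states[vapply(unbound_states, function(s)
    s != disc$unbound_state &&
      sum(C[s, outside]) == 0 && sum(C[outside, s]) == 0, TRUE)]
  mapping <- seq_len(disc$n_states)
  if (length(qual) <= 1)
    return(list(disc = disc, mapping = mapping, n_merged = length(qual)))
  if (is.null(n_new)) n_new <- max(1L, ceiling(length(qual) / 7))
  n_new <- min(n_new, length(qual))
  set.seed(seed)
  cen <- disc$centers[qual, , drop = FALSE]
  km <- if (n_new == 1) list(cluster = rep(1L, length(qual)),
                             centers = matrix(colMeans(cen), 1))
        else suppressWarnings(kmeans(cen, centers = n_new, nstart = 5))
  keep <- setdiff(seq_len(disc$n_states - 1L), qual)
  new_centers <- rbind(disc$centers[keep, , drop = FALSE], km$centers)
  mapping[keep] <- seq_along(keep)
  mapping[qual] <- length(keep) + km$cluster
  mapping[disc$unbound_state] <- nrow(new_centers) + 1L
  new_disc <- structure(list(centers = new_centers, L = disc$L,
                             n_states = nrow(new_centers) + 1L,
                             unbound_state = nrow(new_centers) + 1L),
                        class = "discretization")
  cvc <- unembed_cv(new_centers)
  cvc <- rbind(cvc, data.frame(d = disc$L / 2, alpha1 = NA, alpha2 = NA))
  new_disc$center_cvs <- cvc
  if (!is.null(disc$dtrajs))
    new_disc$dtrajs <- lapply(disc$dtrajs, function(dtr) mapping[dtr])
  list(disc = new_disc, mapping = mapping, n_merged = length(qual))
}
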