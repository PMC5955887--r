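# Independent oracles used across the suite.

# Equilibrium probabilities by direct numerical integration of the Boltzmann
# factor on a (d, alpha1, alpha2) grid.  The configurational measure of two
# uniform points in a periodic square of side L (minimal-image distance) has
# the pair-distance density a(d) = 2*pi*d for d <= L/2 and
# (2*pi - 8*acos(L/(2d)))*d for L/2 < d <= L/sqrt(2); the angles are uniform
# on [0, pi].  `regions` is a named list of functions(d, a1, a2) -> logical.
oracle_equilibrium <- function(world, regions, n_d = 220, n_a = 48) {
  L <- world$box_side
  d <- seq(1e-3, L / sqrt(2), length.out = n_d)
  a <- seq(0, pi, length.out = n_a)
  ad <- ifelse(d <= L / 2, 2 * pi * d,
               (2 * pi - 8 * acos(pmin(1, L / (2 * d)))) * d)
  g <- expand.grid(d = d, a1 = a, a2 = a)
  wgt <- rep(ad, times = n_a * n_a) *
    exp(-world_potential(world, g$d, g$a1, g$a2))
  tot <- sum(wgt)
  vapply(regions, function(f) sum(wgt[f(g$d, g$a1, g$a2)]) / tot, 1)
}

# MBAR-style self-consistent estimator of unbiased state probabilities from
# multiple ensembles with state-wise bias energies; a purely thermodynamic
# route independent of the transition-based TRAM solver.
oracle_mbar_discrete <- function(dtrajs_by_ensemble, bias_energies,
                                 tol = 1e-12, maxiter = 50000) {
  K <- nrow(bias_energies); n <- ncol(bias_energies)
  Nk <- vapply(dtrajs_by_ensemble, function(e) length(unlist(e)), 1)
  counts <- t(vapply(dtrajs_by_ensemble, function(e)
    tabulate(unlist(e), nbins = n), numeric(n)))  # K x n
  Ni <- colSums(counts)
  fk <- rep(0, K)  # per-ensemble free energies
  B <- bias_energies
  for (it in seq_len(maxiter)) {
    # unbiased weight of state i: w_i = N_i / sum_k Nk exp(fk - b_k(i))
    denom <- colSums(Nk * exp(fk - B))
    w <- Ni / denom
    fk_new <- -log(as.vector(exp(-B) %*% w))
    fk_new <- fk_new - fk_new[1]
    if (max(abs(fk_new - fk)) < tol) { fk <- fk_new; break }
    fk <- fk_new
  }
  w <- Ni / colSums(Nk * exp(fk - B))
  w / sum(w)
}

# closed-form forward committor of a 1D birth-death chain with up/down
# probabilities p_i, q_i: q(i) = sum_{k<i} rho_k / sum_{k} rho_k,
# rho_k = prod_{m<=k} q_m/p_m
oracle_committor_birth_death <- function(p_up, p_down) {
  n <- length(p_up) + 2
  rho <- c(1, cumprod(p_down / p_up))
  c(0, cumsum(rho)[seq_len(n - 2)] / sum(rho), 1)[seq_len(n)]
}

# long-run lifetime oracle: slowest relaxation time of bound-component
# indicator autocorrelations, converted to an exit time via the two-state
# relation T_off = tau_relax * (1 - p_bound); frame spacing 2.5 ns
indicator_lifetime_oracle <- function(trajs, indicators, maxlag = 800,
                                      fit_window = c(0.3, 2)) {
  dt_frame <- 2.5e-3
  taus <- vapply(indicators, function(ind) {
    acfs <- NULL; ps <- c()
    for (tr in trajs) {
      x <- as.numeric(ind(tr))
      ps <- c(ps, mean(x))
      acfs <- cbind(acfs, stats::acf(x, lag.max = maxlag, plot = FALSE,
                                     demean = TRUE)$acf[, 1, 1])
    }
    a <- rowMeans(acfs)
    lags <- (0:maxlag) * dt_frame
    sel <- which(lags >= fit_window[1] & lags <= fit_window[2] & a > 0.02)
    tau <- -1 / coef(lm(log(a[sel]) ~ lags[sel]))[[2]]
    tau * (1 - mean(ps))
  }, 1)
  mean(taus)
}

# dense random reversible transition matrix with positive stationary vector
random_reversible_T <- function(n, seed, metastable = FALSE) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.05, 1), n, n)
  W <- (W + t(W)) / 2
  if (metastable) {
    blocks <- sort(rep_len(1:2, n))
    W[outer(blocks, blocks, "!=")] <- W[outer(blocks, blocks, "!=")] * 0.02
    diag(W) <- diag(W) + 3
  }
  list(T = W / rowSums(W), pi = rowSums(W) / sum(W))
}

expect_row_stochastic <- function(T, tol = 1e-10) {
  expect_lt(max(abs(rowSums(T) - 1)), tol)
  expect_gte(min(T), 0)
}
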