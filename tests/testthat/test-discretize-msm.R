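matpow_test <- function(M, k) {
  R <- diag(nrow(M))
  for (i in seq_len(k)) R <- R %*% M
  R
}

test_that("k-means discretization validates input and separates point clouds", {
  far <- structure(data.frame(time = 1:20, d = rep(7.6, 20),
                              alpha1 = runif(20, 0, pi),
                              alpha2 = runif(20, 0, pi)),
                   class = c("cv_trajectory", "data.frame"))
  expect_error(kmeans_discretize(far, 4, L = 15), "nothing to cluster")

  set.seed(8)
  cl1 <- data.frame(d = runif(60, 2.9, 3.1), alpha1 = runif(60, 0.1, 0.3),
                    alpha2 = runif(60, 2.9, 3.1))
  cl2 <- data.frame(d = runif(60, 5.9, 6.1), alpha1 = runif(60, 1.4, 1.6),
                    alpha2 = runif(60, 1.4, 1.6))
  tr <- structure(cbind(time = 1:120, rbind(cl1, cl2)),
                  class = c("cv_trajectory", "data.frame"))
  disc <- kmeans_discretize(tr, 2, L = 15, seed = 1)
  lab <- disc$dtrajs[[1]]
  expect_length(unique(lab[1:60]), 1)
  expect_length(unique(lab[61:120]), 1)
  expect_false(lab[1] == lab[61])
  # frames at d >= L/2 go to the reserved unbound state
  y <- embed_cv(data.frame(d = 7.6, alpha1 = 1, alpha2 = 1))
  expect_identical(assign_microstates(disc, y), disc$unbound_state)
  expect_error(kmeans_discretize(tr[1:3, ], 10, L = 15), "distinct")
})

test_that("sliding-window counts match hand enumeration", {
  dtr <- c(1L, 2L, 1L, 2L)
  C1 <- count_transitions(dtr, 1, n_states = 2)
  expect_equal(unclass(C1), matrix(c(0, 1, 2, 0), 2), ignore_attr = TRUE)
  C2 <- count_transitions(dtr, 2, n_states = 2)
  expect_equal(unclass(C2), matrix(c(1, 0, 0, 1), 2), ignore_attr = TRUE)
  # trajectories are never concatenated
  C <- count_transitions(list(c(1L, 1L), c(2L, 2L)), 1, n_states = 2)
  expect_equal(unclass(C), diag(c(1, 1)), ignore_attr = TRUE)
  expect_warning(count_transitions(list(1L), 1, n_states = 2), "shorter")
  # total sliding-window counts
  set.seed(2)
  dtrs <- list(sample(1:3, 50, TRUE), sample(1:3, 30, TRUE))
  expect_equal(sum(count_transitions(dtrs, 5, n_states = 3)), (50 - 5) + (30 - 5))
})

test_that("reversible MLE reproduces closed forms and satisfies detailed balance", {
  m <- mle_reversible(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
  expect_equal(m$T, matrix(c(0.8, 0.2, 0.2, 0.8), 2), tolerance = 1e-10)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-10)
  expect_error(mle_reversible(matrix(0, 2, 2)), "empty")

  tt <- truth20()
  dtr <- lapply(1:4, function(i) sample_chain(tt, 1, 20000, seed = 100 + i))
  m <- mle_reversible(count_transitions(dtr, 1, n_states = 20))
  expect_row_stochastic(m$T)
  flux <- m$pi * m$T
  expect_lt(max(abs(flux - t(flux))), 1e-8)
  expect_lt(max(abs(as.vector(m$pi %*% m$T) - m$pi)), 1e-8)
})

test_that("the estimator converges to the planted truth with chain length", {
  tt <- truth20()
  err <- vapply(c(4000, 40000), function(n) {
    dtr <- lapply(1:4, function(i) sample_chain(tt, 1, n, seed = 300 + i))
    m <- mle_reversible(count_transitions(dtr, 1, n_states = 20))
    max(abs(m$T[m$active, m$active] - tt$T_true[m$active, m$active]))
  }, 1)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("estimation restricts to the largest connected set and reports drops", {
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 10; C[1, 1] <- 5
  C[3, 4] <- C[4, 3] <- 2   # smaller disconnected pair
  m <- mle_reversible(C)
  expect_identical(m$active, 1:2)
  expect_identical(m$dropped, 3:4)
})

test_that("swap-augmented counts give an exactly swap-symmetric pi", {
  C <- matrix(c(5, 3, 1, 3, 8, 2, 1, 2, 5), 3)
  perm <- c(2L, 1L, 3L)
  Cs <- C + C[perm, perm]          # symmetrize under the relabelling
  m <- mle_reversible(Cs)
  expect_equal(m$pi, m$pi[perm], tolerance = 1e-12)
})

test_that("implied timescales are lag-invariant for a Markov truth and flag Inf", {
  tt <- generate_discrete_truth(2, seed = 9L)
  lam2 <- sum(diag(tt$T_true)) - 1
  ms <- lapply(c(1L, 2L, 5L), function(lag)
    structure(list(T = matpow_test(tt$T_true, lag), pi = tt$pi_true,
                   lag = lag), class = "msm"))
  its <- implied_timescales(ms, n_its = 1)
  expect_equal(its$timescale, rep(-1 / log(lam2), 3), tolerance = 1e-9)
  expect_true(all(attr(its, "converged")[-1, 1]))

  id <- structure(list(T = diag(3), pi = rep(1 / 3, 3), lag = 1L),
                  class = "msm")
  expect_true(all(is.infinite(implied_timescales(list(id), n_its = 2)$timescale)))
})

test_that("bootstrap over trajectories is reproducible and degenerate when identical", {
  tt <- generate_discrete_truth(4, seed = 13L)
  dtr <- sample_chain(tt, 1, 3000, seed = 5L)
  trajs <- list(dtr, dtr, dtr)
  est <- function(trs) mle_reversible(count_transitions(trs, 1, n_states = 4))
  b <- bootstrap_models(trajs, est, n_boot = 5, seed = 3,
                        statistic = function(m) c(p1 = m$pi[1]))
  expect_equal(b$summary$q05, b$summary$q95)  # identical trajectories
  b2 <- bootstrap_models(trajs, est, n_boot = 5, seed = 3,
                         statistic = function(m) c(p1 = m$pi[1]))
  expect_identical(b$stats, b2$stats)
  expect_error(bootstrap_models(trajs[1], est), "two trajectories")
})

test_that("bootstrap intervals cover a known stationary probability", {
  tt <- generate_discrete_truth(6, seed = 15L, n_blocks = 1)
  trajs <- lapply(1:12, function(i) sample_chain(tt, 1, 4000, seed = 40 + i))
  est <- function(trs) mle_reversible(count_transitions(trs, 1, n_states = 6))
  b <- bootstrap_models(trajs, est, n_boot = 20, seed = 8,
                        statistic = function(m) c(p1 = m$pi[1]))
  expect_true(tt$pi_true[1] >= b$summary$q05 - 0.01 &&
                tt$pi_true[1] <= b$summary$q95 + 0.01)
})

test_that("the Chapman-Kolmogorov test passes on Markovian data and flags memory", {
  tt <- generate_discrete_truth(8, seed = 17L, n_blocks = 2, coupling = 0.05)
  dtr <- lapply(1:4, function(i) sample_chain(tt, 1, 15000, seed = 60 + i))
  m <- mle_reversible(count_transitions(dtr, 1, n_states = 8))
  sets <- split(1:8, tt$blocks)
  ck <- ck_test(m, dtr, sets, k_steps = c(1, 2, 5, 10))
  expect_lt(max(ck$abs_dev), 0.03)
  expect_lt(max(ck$abs_dev[ck$k == 1]), 1e-10)  # identical at k = 1

  # non-Markovian observable: lump two states of a 3-state chain whose
  # hidden structure breaks the Chapman-Kolmogorov relation
  W <- matrix(c(20, 1, 0.05, 1, 1, 1, 0.05, 1, 20), 3)
  Th <- W / rowSums(W)
  ph <- rowSums(W) / sum(W)
  set.seed(77)
  hid <- integer(30000); hid[1] <- 1L
  cum <- t(apply(Th, 1, cumsum))
  for (t in 2:30000) hid[t] <- findInterval(runif(1), cum[hid[t - 1], ]) + 1L
  obs <- ifelse(hid == 3L, 2L, 1L)  # states 1,2 merged
  mo <- mle_reversible(count_transitions(obs, 1, n_states = 2))
  cko <- ck_test(mo, list(obs), list(1L, 2L), k_steps = c(1, 20, 60))
  expect_gt(max(cko$abs_dev), 0.05)
})
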