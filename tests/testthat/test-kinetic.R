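test_that("PCCA+ handles block structure, single cluster and rank errors", {
  tr <- random_reversible_T(9, seed = 2, metastable = TRUE)
  cl <- pcca_plus(tr$T, 2, tr$pi)
  blocks <- sort(rep_len(1:2, 9))
  expect_length(unique(paste(cl$labels, blocks)), 2)
  expect_lt(max(abs(rowSums(cl$memberships) - 1)), 1e-10)

  one <- pcca_plus(tr$T, 1)
  expect_identical(one$labels, rep(1L, 9))
  expect_error(pcca_plus(tr$T, 10), "exceeds")
})

test_that("the unbound cluster is detected by distance and angular flatness", {
  pl <- two_basin_pipeline()
  unb <- pl$unbound_tram
  cvs <- pl$disc$center_cvs
  mem <- unb$unbound_microstates
  # the pipeline derives the distance criterion from the world geometry
  # (basin edge at d = 3 + 2 * 0.4 = 3.8 nm)
  expect_true(all(is.na(cvs$d[mem]) | cvs$d[mem] > 3.8))
  # every far, angularly flat microstate ends up in the unbound cluster
  far <- which(cvs$d > 4.2 | is.na(cvs$d))
  expect_gt(length(intersect(far, mem)) / length(far), 0.9)
  # a fully bound model has no unbound cluster
  tr <- random_reversible_T(8, seed = 3, metastable = TRUE)
  disc_b <- structure(list(
    centers = embed_cv(data.frame(d = runif(8, 2.8, 3.4),
                                  alpha1 = runif(8, 0, pi),
                                  alpha2 = runif(8, 0, pi))),
    L = 15, n_states = 8L, unbound_state = 99L,
    center_cvs = data.frame(d = runif(8, 2.8, 3.4),
                            alpha1 = runif(8, 0, pi),
                            alpha2 = runif(8, 0, pi))),
    class = "discretization")
  m <- structure(list(T = tr$T, pi = tr$pi, lag = 1L, active = 1:8),
                 class = "msm")
  expect_error(select_unbound(m, disc_b, n_max = 6), "no unbound cluster")
})

test_that("disconnected components are found and labelled by orientation", {
  # toy: 5 clusters; cluster 5 = unbound hub, bound pairs (1,2) and (3,4)
  # exchange only through it; means place (1,2) at (0,pi), (3,4) at (pi,pi)
  cvs <- data.frame(
    d = c(3, 3.2, 3, 3.2, 7),
    alpha1 = c(0.2, 0.3, 2.9, 2.8, 1.5),
    alpha2 = c(2.9, 2.8, 2.9, 3.0, 1.6))
  disc <- structure(list(centers = embed_cv(cvs), L = 15, n_states = 5L,
                         unbound_state = 99L, center_cvs = cvs),
                    class = "discretization")
  C <- matrix(0L, 5, 5)
  C[1, 2] <- C[2, 1] <- 4; C[3, 4] <- C[4, 3] <- 4
  for (s in 1:4) { C[s, 5] <- C[5, s] <- 2 }
  diag(C) <- 10L
  model <- structure(list(T = diag(5), pi = rep(0.2, 5), lag = 1L,
                          active = 1:5), class = "msm")
  clustering <- structure(list(labels = 1:5, n_clusters = 5L,
                               memberships = diag(5),
                               sets = as.list(1:5)), class = "pcca")
  dc <- disconnected_components(clustering, C, model, disc,
                                unbound_cluster = 5)
  expect_length(dc$components, 2)
  expect_setequal(dc$labels, c("C0pi", "Cpipi"))
  # fully connected bound set -> one component
  C2 <- C; C2[2, 3] <- C2[3, 2] <- 1
  dc2 <- disconnected_components(clustering, C2, model, disc, 5)
  expect_length(dc2$components, 1)
})

test_that("component labels follow the quarter-turn windows", {
  pl <- two_basin_pipeline()
  dc <- pl$decomp_tram
  expect_setequal(dc$labels, c("C0pi", "Cpi0"))
  for (i in seq_along(dc$labels)) {
    m <- dc$mean_angles[i, ]
    if (dc$labels[i] == "C0pi") {
      expect_lt(m[1], pi / 4); expect_gt(m[2], 3 * pi / 4)
    } else {
      expect_gt(m[1], 3 * pi / 4); expect_lt(m[2], pi / 4)
    }
  }
})

test_that("macrostates merge mirror clusters across the asymmetric pair", {
  pl <- two_basin_pipeline()
  mac <- pl$macrostates
  # the two asymmetric components pair into macrostates spanning both
  expect_true(any(grepl("\\+", mac$component)))
  # weights aggregate the component weights
  expect_equal(sum(mac$weight), sum(pl$decomp_tram$weights), tolerance = 1e-9)
})

test_that("coarse-graining preserves aggregation identities and cross-relaxation", {
  # identity partition returns T unchanged
  tr <- random_reversible_T(7, seed = 5)
  cg0 <- coarse_grain(tr$T, tr$pi, as.list(1:7))
  expect_lt(max(abs(cg0$T_cg - tr$T)), 1e-10)

  # block-uncoupled chain with the block partition -> identity matrix
  Tb <- rbind(cbind(matrix(c(.9, .1, .1, .9), 2), matrix(0, 2, 2)),
              cbind(matrix(0, 2, 2), matrix(c(.8, .2, .2, .8), 2)))
  pib <- rep(0.25, 4)
  cgb <- coarse_grain(Tb, pib, list(1:2, 3:4))
  expect_equal(cgb$T_cg, diag(2), tolerance = 1e-10)

  # random reversible chains: pi_cg is the exact aggregation, rows sum to 1,
  # pi_cg is exactly stationary, and for a metastable 2-block system the
  # coarse relaxation time matches the full model's slowest cross relaxation
  for (seed in 1:3) {
    tr <- random_reversible_T(6 + 2 * seed, seed = seed, metastable = TRUE)
    n <- nrow(tr$T)
    part <- split(seq_len(n), sort(rep_len(1:2, n)))
    cg <- coarse_grain(tr$T, tr$pi, part)
    expect_equal(cg$pi_cg, vapply(part, function(I) sum(tr$pi[I]), 1),
                 tolerance = 1e-14)
    expect_lt(max(abs(rowSums(cg$T_cg) - 1)), 1e-10)
    expect_lt(max(abs(as.vector(cg$pi_cg %*% cg$T_cg) - cg$pi_cg)), 1e-10)
    lam2 <- sort(Re(eigen(tr$T, only.values = TRUE)$values), TRUE)[2]
    lam2cg <- sort(Re(eigen(cg$T_cg, only.values = TRUE)$values), TRUE)[2]
    # the construction matches zero-frequency correlations; for a strongly
    # metastable partition the slow eigenvalue is preserved near-exactly
    expect_equal(lam2cg, lam2, tolerance = 1e-4)
  }
  expect_error(coarse_grain(tr$T, tr$pi, list(1:3)), "cover every state")
})

test_that("coarse occupation curves track the microscopic model at least as well as projection", {
  tr <- random_reversible_T(10, seed = 9, metastable = TRUE)
  part <- split(1:10, sort(rep_len(1:2, 10)))
  cg <- coarse_grain(tr$T, tr$pi, part)
  # naive projection coarse graining: local-equilibrium average of T
  Tproj <- matrix(0, 2, 2)
  for (I in 1:2) for (J in 1:2)
    Tproj[I, J] <- sum(tr$pi[part[[I]]] *
                         rowSums(tr$T[part[[I]], part[[J]], drop = FALSE])) /
      sum(tr$pi[part[[I]]])
  occ_micro <- function(k) {
    Tk <- diag(10); for (i in seq_len(k)) Tk <- Tk %*% tr$T
    vapply(1:2, function(I) {
      w <- tr$pi[part[[I]]] / sum(tr$pi[part[[I]]])
      sum(w * rowSums(Tk[part[[I]], part[[I]], drop = FALSE]))
    }, 1)
  }
  occ_cg <- function(M, k) {
    Mk <- diag(2); for (i in seq_len(k)) Mk <- Mk %*% M
    diag(Mk)
  }
  dev_opt <- dev_proj <- 0
  for (k in c(1, 2, 5, 10, 20)) {
    om <- occ_micro(k)
    dev_opt <- max(dev_opt, max(abs(occ_cg(cg$T_cg, k) - om)))
    dev_proj <- max(dev_proj, max(abs(occ_cg(Tproj, k) - om)))
  }
  expect_lte(dev_opt, dev_proj + 1e-12)
})

test_that("committors obey closed forms, bounds and monotonicity", {
  # asymmetric birth-death chain vs the closed-form ratio of sums
  n <- 7
  p_up <- c(0.3, 0.25, 0.4, 0.2, 0.35)
  p_down <- c(0.2, 0.35, 0.1, 0.3, 0.25)
  T <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    T[i, i + 1] <- p_up[i - 1]; T[i, i - 1] <- p_down[i - 1]
    T[i, i] <- 1 - p_up[i - 1] - p_down[i - 1]
  }
  T[1, 1] <- 0.7; T[1, 2] <- 0.3
  T[n, n] <- 0.6; T[n, n - 1] <- 0.4
  q <- committor(T, source = 1, sink = n)
  expect_equal(q, oracle_committor_birth_death(p_up, p_down),
               tolerance = 1e-10)
  expect_true(all(diff(q) >= -1e-12))  # monotone along the chain
  expect_equal(q[n], 1)
  # symmetric chain midpoint
  Ts <- matrix(0, 5, 5)
  for (i in 2:4) { Ts[i, i - 1] <- Ts[i, i + 1] <- 0.25; Ts[i, i] <- 0.5 }
  Ts[1, ] <- c(0.8, 0.2, 0, 0, 0); Ts[5, ] <- c(0, 0, 0, 0.2, 0.8)
  expect_equal(committor(Ts, 1, 5)[3], 0.5, tolerance = 1e-12)
  expect_error(committor(Ts, 1, 1), "disjoint")
})

test_that("umbrella centres are selected by committor threshold", {
  pl <- two_basin_pipeline()
  cen <- pl$umbrella_centers
  expect_true(all(cen$committor > 0.1))
  expect_true(all(cen$component %in% seq_along(pl$decomp$microstates)))
  # threshold 1 excludes everything except (possibly) the sink itself
  sel1 <- select_umbrella_centers(pl$prelim, pl$disc0, pl$decomp,
                                  threshold = 1)
  expect_true(is.null(sel1) || all(sel1$committor >= 1))
  # threshold 0 selects every state with nonzero committor per component
  sel0 <- select_umbrella_centers(pl$prelim, pl$disc0, pl$decomp,
                                  threshold = 0)
  expect_gte(nrow(sel0), nrow(cen))
})

test_that("flux decomposition recovers planted pathway splits", {
  # linear chain: one pathway carrying all flux
  T <- matrix(0, 3, 3)
  T[1, 2] <- 0.5; T[1, 1] <- 0.5
  T[2, 1] <- 0.25; T[2, 3] <- 0.25; T[2, 2] <- 0.5
  T[3, 2] <- 0.5; T[3, 3] <- 0.5
  pi <- stationary_distribution(T)
  fp <- flux_partition(T, pi, source = 1, sink = 3)
  expect_length(fp$pathways, 1)
  expect_equal(fp$fraction, 1, tolerance = 1e-10)

  # two parallel channels planted as a reversible chain (symmetric edge
  # weights); channel conductances in ratio r:1 split the flux r:1
  two_channel <- function(r) {
    W <- matrix(0, 4, 4)
    W[1, 2] <- W[2, 1] <- r; W[2, 4] <- W[4, 2] <- r
    W[1, 3] <- W[3, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
    diag(W) <- 4 * r
    W / rowSums(W)
  }
  Teq <- two_channel(1)
  fpe <- flux_partition(Teq, stationary_distribution(Teq), 1, 4)
  expect_equal(sort(fpe$fraction), c(0.5, 0.5), tolerance = 1e-10)
  T91 <- two_channel(9)
  fp91 <- flux_partition(T91, stationary_distribution(T91), 1, 4)
  expect_equal(sort(fp91$fraction, TRUE), c(0.9, 0.1), tolerance = 1e-10)
  # zero flux errors
  Tz <- diag(4)
  expect_error(flux_partition(Tz, rep(0.25, 4), 1, 4), "singular|zero")
})
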