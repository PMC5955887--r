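#' Association/escape fractions at the escape distance
#'
#' Scans unbiased trajectories for episodes that start when the
#' inter-protomer distance crosses the encounter distance r0 and follow
#' until either an associated (bound, non-unbound-cluster) microstate is
#' entered or the distance reaches the escape distance r1 > r0.  `f_ass`
#' is the fraction of episodes that associate; `f_esc = 1 - f_ass`.
#'
#' @param trajs list of `cv_trajectory` objects.
#' @param disc discretization used to recognize bound microstates.
#' @param unbound_states microstates of the unbound cluster.
#' @param r0,r1 encounter and escape distances (nm).
#' @return list with `f_ass`, `f_esc`, `n_episodes`.
#' @export
estimate_capture_fractions <- function(trajs, disc, unbound_states, r0, r1) {
  if (r1 <= r0) stop("need r1 > r0")
  n_ass <- 0L; n_esc <- 0L
  for (tr in trajs) {
    d <- tr$d
    bound <- !(assign_microstates(disc, tr) %in% unbound_states)
    t <- 1L
    n <- length(d)
    while (t < n) {
      # episode start: crossing of r0 while not bound
      cross <- which((d[-n] - r0) * (d[-1] - r0) <= 0 &
                       !bound[-n] & seq_len(n - 1) >= t)[1]
      if (is.na(cross)) break
      s <- cross + 1L
      res <- NA
      while (s <= n) {
        if (bound[s]) { res <- "ass"; break }
        if (d[s] >= r1) { res <- "esc"; break }
        s <- s + 1L
      }
      if (is.na(res)) break
      if (res == "ass") n_ass <- n_ass + 1L else n_esc <- n_esc + 1L
      t <- s + 1L
    }
  }
  tot <- n_ass + n_esc
  if (tot == 0) stop("no encounter episodes found")
  list(f_ass = n_ass / tot, f_esc = n_esc / tot, n_episodes = tot)
}

#' Full dimerization-kinetics pipeline on a synthetic world
#'
#' Runs the complete analysis: unbiased Brownian-dynamics sampling,
#' protomer-swap augmentation, k-means discretization, a preliminary
#' reversible MSM, detection of the unbound PCCA+ cluster and of the
#' kinetically disconnected orientational components, committor-based
#' umbrella-centre selection, umbrella sampling, silent-unbound-state
#' resampling, the TRAM multi-ensemble estimate, component analysis and
#' macrostate assembly on the TRAM matrix, cross-relaxation-preserving
#' coarse-graining to the component level, and the reaction-diffusion
#' concentration scan.
#'
#' @param world a [synthetic_world()].
#' @param n_traj,n_steps,dt,stride unbiased sampling (see
#'   [simulate_unbiased()]).
#' @param lag MSM lag in recorded frames.
#' @param n_centers number of k-means microstates.
#' @param n_umbrella number of umbrella windows (committor-selected centres
#'   are subsampled evenly if more are eligible); 0 disables umbrella
#'   sampling and TRAM runs on the unbiased ensemble alone.
#' @param umbrella_steps,k_d,k_alpha umbrella-window sampling and restraint
#'   strength.
#' @param tram_tol TRAM convergence threshold (kT).
#' @param tram_stride frame stride for the TRAM free-energy sums.
#' @param d_min unbound-cluster distance criterion (nm).  By default it is
#'   derived from the world geometry as the outer edge of the binding
#'   basins, `max(d + 2 * width_d)` over the wells: the criterion must sit
#'   in the gap between the bound basins and the encounter zone, and a
#'   fixed literature value only fits receptors of the matching size.
#' @param seed base seed for every stage.
#' @param time_scale clock rescaling for final rates/times (1 for synthetic
#'   data, 4 for Martini-derived trajectories).
#' @param c_grid concentrations for the scan (\eqn{\mu m^{-2}}).
#' @param contact_frames number of frames decorated for contact analysis.
#' @return list with the intermediate objects (`disc`, `prelim`, `decomp`,
#'   `tram`, `decomp_tram`, `macrostates`, `cg`, `rates`, `scan`,
#'   `contacts`, ...).
#' @export
run_dimer_pipeline <- function(world,
                               n_traj = 24, n_steps = 40000, dt = 5e-4,
                               stride = 5L, lag = 20L,
                               n_centers = 120L,
                               n_umbrella = 12L, umbrella_steps = 6000,
                               k_d = 97, k_alpha = 39,
                               tram_tol = 1e-9, tram_stride = 2L,
                               d_min = NULL, seed = 1L,
                               time_scale = 1,
                               c_grid = 10^seq(0, 4, by = 0.5),
                               contact_frames = 400L) {
  L <- world$box_side
  if (is.null(d_min)) {
    d_min <- if (nrow(world$wells) > 0)
      max(world$wells$d + 2 * world$wells$width_d) else 4.2
  }
  sims <- simulate_unbiased(world, n_traj, n_steps, dt = dt, stride = stride,
                            seed = seed)
  aug <- swap_augment(sims)
  disc0 <- kmeans_discretize(aug, n_centers, L, seed = seed)
  counts0 <- count_transitions(disc0$dtrajs, lag, n_states = disc0$n_states)
  prelim <- mle_reversible(counts0)
  unb <- select_unbound(prelim, disc0, d_min = d_min)
  decomp <- disconnected_components(unb$clustering, counts0, prelim, disc0,
                                    unb$cluster)
  centers <- select_umbrella_centers(prelim, disc0, decomp, threshold = 0.1)

  res <- resample_unbound(disc0, counts0, unb$unbound_microstates,
                          seed = seed)
  disc <- res$disc

  ensembles <- list(ensemble_data(aug, bias = NULL, id = "unbiased"))
  if (n_umbrella > 0 && nrow(centers) > 0) {
    pick <- centers[order(centers$component, -centers$committor), ]
    pick <- pick[!is.na(pick$alpha1), ]
    idx <- unique(round(seq(1, nrow(pick),
                            length.out = min(n_umbrella, nrow(pick)))))
    for (w in idx) {
      bs <- bias_spec(pick$d[w], pick$alpha1[w], pick$alpha2[w],
                      k_d = k_d, k_alpha = k_alpha)
      utr <- simulate_umbrella(world, bs, umbrella_steps, dt = dt,
                               stride = stride, seed = seed + 1000L + w)
      ensembles[[length(ensembles) + 1]] <-
        ensemble_data(utr, bias = bs, id = paste0("umbrella", w))
    }
  }
  tram <- tram_estimate(ensembles, disc, lag, tol = tram_tol,
                        stride = tram_stride)
  counts <- count_transitions(lapply(aug, function(tr)
    assign_microstates(disc, tr)), lag, n_states = disc$n_states)

  unb2 <- select_unbound(tram, disc, d_min = d_min)
  decomp2 <- disconnected_components(unb2$clustering, counts, tram, disc,
                                     unb2$cluster)
  macro <- assemble_macrostates(decomp2, tram, disc)

  # component-level reduced model: unbound cluster first, then components
  act <- tram$active
  part <- c(list(match(decomp2$unbound_microstates, act)),
            lapply(decomp2$microstates, function(m) match(m, act)))
  pi_act <- tram$pi[act] / sum(tram$pi[act])
  # tolerate statistical-noise negatives in the aggregated fundamental
  # matrix (clipped and renormalized); genuinely inconsistent partitions
  # still error out
  cg <- coarse_grain(tram$T, pi_act, part, neg_tol = 0.01)

  lag_time <- lag * dt * stride
  rates <- component_rates(cg$T_cg, lag_time, time_scale = time_scale,
                           labels = decomp2$labels)

  r0 <- estimate_r0(tram$pi, disc$center_cvs$d,
                    decomp2$unbound_microstates)
  r1 <- min(r0 + 0.8, 0.99 * L / 2)
  capt <- estimate_capture_fractions(aug, disc,
                                     decomp2$unbound_microstates, r0, r1)
  D_rel <- 2 * world$diffusion_translation  # nm^2/us == um^2/s
  c_sim <- 2 / (L * 1e-3)^2
  params <- rd_params(D = D_rel, r0 = r0, r1 = r1,
                      f_ass = capt$f_ass, f_esc = capt$f_esc,
                      c_grid = c_grid, c_sim = c_sim)
  scan <- concentration_scan(rates, params)

  contacts <- NULL
  if (contact_frames > 0) {
    tpl <- mor_bead_template()
    pool <- do.call(rbind, lapply(sims, function(tr)
      tr[, c("d", "alpha1", "alpha2")]))
    take <- unique(round(seq(1, nrow(pool),
                             length.out = min(contact_frames, nrow(pool)))))
    sub <- pool[take, ]
    frames <- decorate_beads(sub, tpl, L)
    dtraj <- assign_microstates(disc, sub)
    stats <- microstate_stats(dtraj, frames, disc$n_states)
    maps <- lapply(seq_len(nrow(macro)), function(i)
      macrostate_contact_map(stats, tram$pi, macro$microstates[[i]]))
    labels <- vapply(maps, name_interface, "")
    contacts <- list(stats = stats, maps = maps, interface = labels)
  }

  list(world = world, sims = sims, disc0 = disc0, disc = disc,
       prelim = prelim, unbound = unb, decomp = decomp,
       umbrella_centers = centers, ensembles = ensembles,
       tram = tram, counts = counts, unbound_tram = unb2,
       decomp_tram = decomp2, macrostates = macro, cg = cg,
       rates = rates, r0 = r0, capture = capt, params = params,
       scan = scan, contacts = contacts)
}
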