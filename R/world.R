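#' Synthetic two-protomer world
#'
#' Defines a reduced model of two membrane-embedded protomers: two orientable
#' points diffusing in a periodic square patch of membrane, interacting
#' through Gaussian wells placed on the collective variables
#' \eqn{(d, \alpha_1, \alpha_2)} -- the inter-protomer centre-of-mass
#' distance and the two unsigned orientation angles.  Energies are in units
#' of kT (reduced units); lengths in nm; times in \eqn{\mu}s.
#'
#' @param box_side side length of the periodic membrane patch (nm).
#' @param diffusion_translation translational diffusion constant of one
#'   protomer (nm\eqn{^2}/\eqn{\mu}s).
#' @param diffusion_rotation rotational diffusion constant
#'   (rad\eqn{^2}/\eqn{\mu}s).
#' @param wells data frame with one row per Gaussian well and columns
#'   `d` (centre distance, nm), `alpha1`, `alpha2` (centre angles, rad, in
#'   \[0, pi\]), `depth` (kT, >= 0), `width_d` (nm) and `width_alpha` (rad).
#' @param wall_height,wall_center,wall_width short-range steric repulsion,
#'   an exponential wall \eqn{h \exp(-(d - c)/w)} independent of
#'   orientation, unbounded at short range.  Binding wells are carved
#'   through the wall (their depth must exceed the wall energy at the well
#'   centre to be attractive), so protomers in contact cannot re-orient
#'   without first separating -- the steric locking that makes
#'   orientational components kinetically disconnected.
#'   `wall_height = 0` disables the wall.
#' @param temperature_kT thermal energy unit; 1 in reduced units.
#' @param seed base random seed; trajectory `i` of a batch uses `seed + i - 1`.
#' @return An object of class `synthetic_world`.
#' @seealso [simulate_unbiased()], [simulate_umbrella()], [world_potential()]
#' @export
synthetic_world <- function(box_side = 15,
                            diffusion_translation = 5,
                            diffusion_rotation = 0.3,
                            wells = NULL,
                            wall_height = 0, wall_center = 3.0,
                            wall_width = 0.3,
                            temperature_kT = 1,
                            seed = 1L) {
  if (is.null(wells)) {
    wells <- data.frame(d = numeric(), alpha1 = numeric(), alpha2 = numeric(),
                        depth = numeric(), width_d = numeric(),
                        width_alpha = numeric())
  }
  wells <- as.data.frame(wells)
  req <- c("d", "alpha1", "alpha2", "depth", "width_d", "width_alpha")
  if (!all(req %in% names(wells)))
    stop("wells must have columns: ", paste(req, collapse = ", "))
  if (nrow(wells) > 0) {
    if (any(wells$depth < 0)) stop("well depths must be >= 0")
    if (any(wells$width_d <= 0) || any(wells$width_alpha <= 0))
      stop("well widths must be > 0")
    if (box_side <= 2 * max(wells$d))
      stop("box_side must exceed twice the largest well distance")
    if (any(wells$alpha1 < 0 | wells$alpha1 > pi |
            wells$alpha2 < 0 | wells$alpha2 > pi))
      stop("well angles must lie in [0, pi]")
  }
  if (box_side <= 0 || diffusion_translation <= 0 || diffusion_rotation <= 0)
    stop("box_side and diffusion constants must be positive")
  if (wall_height < 0 || wall_width <= 0)
    stop("wall_height must be >= 0 and wall_width > 0")
  structure(list(box_side = box_side,
                 diffusion_translation = diffusion_translation,
                 diffusion_rotation = diffusion_rotation,
                 wells = wells,
                 wall = c(height = wall_height, center = wall_center,
                          width = wall_width),
                 temperature_kT = temperature_kT,
                 seed = as.integer(seed)),
            class = "synthetic_world")
}

#' Receptor-like default world
#'
#' A world with four bound basins at distance 3 nm, one for each combination
#' of the two interface orientations (\eqn{\alpha \approx 0}: the TM1/TM2/H8
#' face; \eqn{\alpha \approx \pi}: the TM4/TM5/TM6 face), carved through a
#' steric wall so that re-orientation at contact is forbidden and the four
#' basins form kinetically disconnected components connected only through
#' the unbound state.  The asymmetric basins are deepest, mimicking the
#' dominance of asymmetric dimers in coarse-grained receptor simulations.
#' Depths are raw well depths in kT; the effective binding energy at the
#' basin centre is the depth minus the wall energy there (about
#' `wall_height`, since the basin centre sits at the wall reference
#' distance).
#'
#' @param depth_asym,depth_pp,depth_00 well depths (kT) for the asymmetric
#'   (0,pi)/(pi,0) pair, the (pi,pi) basin and the (0,0) basin.
#' @param d_bind basin centre distance (nm).
#' @param width_d,width_alpha basin widths (nm, rad).
#' @param wall_height steric wall height (kT).
#' @param ... passed on to [synthetic_world()].
#' @export
mor_like_world <- function(depth_asym = 11.5, depth_pp = 11, depth_00 = 10.5,
                           d_bind = 3, width_d = 0.4, width_alpha = 0.5,
                           wall_height = 6, ...) {
  wells <- data.frame(
    d = d_bind,
    alpha1 = c(0, pi, pi, 0),
    alpha2 = c(pi, 0, pi, 0),
    depth = c(depth_asym, depth_asym, depth_pp, depth_00),
    width_d = width_d,
    width_alpha = width_alpha)
  synthetic_world(wells = wells, wall_height = wall_height, ...)
}

#' Interaction potential of a synthetic world
#'
#' Evaluates the Gaussian-well interaction energy (in kT) on the collective
#' variables.  Vectorized over frames; used both for analysis and as the
#' target density of equilibrium oracles.
#'
#' @param world a [synthetic_world()].
#' @param d,alpha1,alpha2 numeric vectors of equal length.
#' @return numeric vector of reduced energies U/kT.
#' @export
world_potential <- function(world, d, alpha1, alpha2) {
  stopifnot(inherits(world, "synthetic_world"))
  U <- numeric(length(d))
  wl <- world$wall
  if (!is.null(wl) && wl[["height"]] > 0)
    U <- U + wl[["height"]] * exp(-(d - wl[["center"]]) / wl[["width"]])
  w <- world$wells
  if (nrow(w) == 0) return(U)
  for (i in seq_len(nrow(w))) {
    U <- U - w$depth[i] * exp(-0.5 * (((d - w$d[i]) / w$width_d[i])^2 +
                                      ((alpha1 - w$alpha1[i]) / w$width_alpha[i])^2 +
                                      ((alpha2 - w$alpha2[i]) / w$width_alpha[i])^2))
  }
  U
}

#' Harmonic umbrella restraint
#'
#' A harmonic bias \eqn{U_b = \tfrac12 k_d (d-d_0)^2 + \tfrac12 k_\alpha
#' [(\alpha_1-\alpha_{1,0})^2 + (\alpha_2-\alpha_{2,0})^2]} on the collective
#' variables, as used for umbrella-sampling windows.
#'
#' @param d,alpha1,alpha2 restraint centre (nm, rad, rad); angles in \[0, pi\].
#' @param k_d distance force constant (energy/nm^2, >= 0).
#' @param k_alpha angle force constant (energy/rad^2, >= 0).
#' @return An object of class `bias_spec`.
#' @export
bias_spec <- function(d, alpha1, alpha2, k_d, k_alpha) {
  if (k_d < 0 || k_alpha < 0) stop("force constants must be >= 0")
  if (alpha1 < 0 || alpha1 > pi || alpha2 < 0 || alpha2 > pi)
    stop("restraint angles must lie in [0, pi]")
  if (d < 0) stop("restraint distance must be >= 0")
  structure(list(d = d, alpha1 = alpha1, alpha2 = alpha2,
                 k_d = k_d, k_alpha = k_alpha), class = "bias_spec")
}

#' Bias energy of frames under a restraint
#'
#' @param spec a [bias_spec()] or `NULL` (no bias; returns zeros).
#' @param d,alpha1,alpha2 frame collective variables.
#' @param kT thermal energy in the same units as the force constants; the
#'   returned energies are reduced (divided by `kT`).
#' @return numeric vector, U_b/kT per frame.
#' @export
bias_energy <- function(spec, d, alpha1, alpha2, kT = 1) {
  if (is.null(spec)) return(numeric(length(d)))
  stopifnot(inherits(spec, "bias_spec"))
  (0.5 * spec$k_d * (d - spec$d)^2 +
   0.5 * spec$k_alpha * ((alpha1 - spec$alpha1)^2 +
                         (alpha2 - spec$alpha2)^2)) / kT
}

new_cv_trajectory <- function(df, ensemble = "unbiased", bias = NULL,
                              dt = NULL) {
  structure(df, class = c("cv_trajectory", "data.frame"),
            ensemble = ensemble, bias = bias, dt = dt)
}

#' Simulate unbiased trajectories
#'
#' Runs overdamped Langevin (Euler--Maruyama) dynamics of the two protomers
#' and records the collective variables.  Each trajectory gets its own seed,
#' `seed + i - 1`, so individual trajectories are reproducible in isolation.
#'
#' @param world a [synthetic_world()].
#' @param n_traj number of independent trajectories.
#' @param n_steps integration steps per trajectory.
#' @param dt time step (\eqn{\mu}s); per-step displacements must stay well
#'   below the well widths.
#' @param stride record every `stride`-th step.
#' @param seed base seed (default: the world's).
#' @return list of `cv_trajectory` data frames with columns
#'   `time`, `d`, `alpha1`, `alpha2`.
#' @export
simulate_unbiased <- function(world, n_traj, n_steps, dt = 5e-4, stride = 1L,
                              seed = world$seed) {
  stopifnot(inherits(world, "synthetic_world"))
  check_dt(world, dt)
  wells <- as.matrix(world$wells[, c("d", "alpha1", "alpha2", "depth",
                                     "width_d", "width_alpha")])
  lapply(seq_len(n_traj), function(i) {
    set.seed(seed + i - 1L)
    m <- .bd_simulate_cpp(wells, unname(world$wall), world$box_side,
                          world$diffusion_translation, world$diffusion_rotation,
                          as.integer(n_steps), dt, as.integer(stride),
                          numeric(0), numeric(0))
    new_cv_trajectory(data.frame(time = m[, 1], d = m[, 2],
                                 alpha1 = m[, 3], alpha2 = m[, 4]),
                      ensemble = "unbiased", dt = dt * stride)
  })
}

#' Simulate an umbrella-restrained trajectory
#'
#' Same dynamics as [simulate_unbiased()] with an added harmonic restraint;
#' each recorded frame carries its reduced bias energy.  The trajectory is
#' started at the restraint centre.
#'
#' @inheritParams simulate_unbiased
#' @param bias a [bias_spec()].
#' @param seed random seed for this window.
#' @return a `cv_trajectory` with an extra `bias_energy` column.
#' @export
simulate_umbrella <- function(world, bias, n_steps, dt = 5e-4, stride = 1L,
                              seed = world$seed) {
  stopifnot(inherits(world, "synthetic_world"), inherits(bias, "bias_spec"))
  if (bias$d >= world$box_side / 2)
    stop("bias centre must lie inside the box (d < box_side/2)")
  check_dt(world, dt)
  wells <- as.matrix(world$wells[, c("d", "alpha1", "alpha2", "depth",
                                     "width_d", "width_alpha")])
  set.seed(seed)
  # start at the restraint centre: protomer 1 at box centre, protomer 2 at
  # distance d0 along +x, orientations matching the centre angles
  L <- world$box_side
  start <- c(L / 2, L / 2, L / 2 + bias$d, L / 2, bias$alpha1, pi - bias$alpha2)
  m <- .bd_simulate_cpp(wells, unname(world$wall), L,
                        world$diffusion_translation, world$diffusion_rotation,
                        as.integer(n_steps), dt, as.integer(stride),
                        c(bias$d, bias$alpha1, bias$alpha2,
                          bias$k_d / world$temperature_kT,
                          bias$k_alpha / world$temperature_kT),
                        start)
  new_cv_trajectory(data.frame(time = m[, 1], d = m[, 2], alpha1 = m[, 3],
                               alpha2 = m[, 4], bias_energy = m[, 5]),
                    ensemble = "umbrella", bias = bias, dt = dt * stride)
}

check_dt <- function(world, dt) {
  step_t <- sqrt(2 * world$diffusion_translation * dt)
  if (nrow(world$wells) > 0 && step_t > 0.5 * min(world$wells$width_d))
    stop("dt too large: per-step displacement exceeds half the well width")
  invisible(TRUE)
}
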