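#' Relative 2D diffusion constant from distance fluctuations
#'
#' Fits the lag dependence of the variance of the inter-protomer distance
#' increments, restricted to frames inside a distance window far from
#' contact, where the radial increment variance grows as
#' \eqn{2 D_{rel} \, lag}.  The relative diffusion constant is the sum of
#' the two protomers' translational diffusion constants.
#'
#' @param trajs list of `cv_trajectory` objects.
#' @param d_window distances (nm) defining the analysis window.
#' @param max_lag largest lag, in frames.
#' @return list with `D` (nm^2 per frame-time unit if `dt` attributes are
#'   set, else per frame), `stderr`, and the per-lag variance table.
#' @export
estimate_diffusion <- function(trajs, d_window = c(8, 11), max_lag = 20L) {
  if (inherits(trajs, "cv_trajectory")) trajs <- list(trajs)
  dt <- attr(trajs[[1]], "dt") %||% 1
  lags <- seq_len(max_lag)
  v <- rep(NA_real_, max_lag); nn <- integer(max_lag)
  for (lag in lags) {
    incs <- unlist(lapply(trajs, function(tr) {
      d <- tr$d
      n <- length(d)
      if (n <= lag) return(numeric(0))
      i <- seq_len(n - lag)
      ok <- d[i] >= d_window[1] & d[i] <= d_window[2]
      (d[i + lag] - d[i])[ok]
    }))
    nn[lag] <- length(incs)
    if (length(incs) >= 2) v[lag] <- var(incs)
  }
  if (sum(nn) < 10) stop("too few frames inside the distance window")
  tab <- data.frame(lag = lags * dt, var = v, n = nn)
  fit <- lm(var ~ lag + 0, data = tab[!is.na(tab$var), ])
  list(D = unname(coef(fit)[1]) / 2,
       stderr = unname(summary(fit)$coefficients[1, 2]) / 2,
       table = tab)
}

#' Encounter distance from the unbound cluster
#'
#' The stationary-weighted mean inter-protomer distance over the unbound
#' cluster's microstates, \eqn{r_0 = \sum_{i \in U} d_i \pi_i / \sum \pi_i}.
#'
#' @param pi stationary probabilities over microstates.
#' @param center_d distance of each microstate centre (nm).
#' @param unbound integer indices of the unbound cluster's microstates.
#' @return r0 in nm.
#' @export
estimate_r0 <- function(pi, center_d, unbound) {
  if (!length(unbound)) stop("empty unbound cluster")
  w <- pi[unbound]
  sum(center_d[unbound] * w) / sum(w)
}

#' Diffusive 2D association rate coefficient
#'
#' \eqn{k_{+1} = 4 \pi D / \ln(\lambda / r_0)} with the mean free path
#' \eqn{\lambda = (\pi c)^{-1/2}} at 2D concentration c.  `k_plus1 * c` is
#' a first-order rate.
#'
#' @param c 2D concentration (\eqn{\mu m^{-2}}); vectorized.
#' @param D relative diffusion constant (\eqn{\mu m^2/s}).
#' @param r0 encounter distance (nm).
#' @return k_plus1 in \eqn{\mu m^2/s}.
#' @export
k_plus1 <- function(c, D, r0) {
  lambda <- mean_free_path(c)
  r0_um <- r0 * 1e-3
  if (any(lambda <= r0_um))
    stop("concentration too high: mean free path does not exceed r0")
  4 * pi * D / log(lambda / r0_um)
}

#' Mean free path at a 2D concentration
#'
#' @param c concentration (\eqn{\mu m^{-2}}).
#' @return \eqn{\lambda = (\pi c)^{-1/2}} in \eqn{\mu m}.
#' @export
mean_free_path <- function(c) 1 / sqrt(pi * c)

#' Capture probability of the encounter complex
#'
#' Northrup-Allison-McCammon closure:
#' \eqn{\gamma = f_{ass}(r_1) / (1 - f_{esc}(r_1) p_{ass}(r_1))} with
#' \eqn{p_{ass} = 1 - \ln(\lambda/r_1) / \ln(\lambda/r_0)}, the probability
#' that a trajectory reaching the escape distance \eqn{r_1} returns to
#' \eqn{r_0} instead of escaping to the mean free path \eqn{\lambda}.
#'
#' @param f_ass fraction of trajectories started at r0 that associate
#'   before reaching r1.
#' @param f_esc fraction that reach r1 before associating.
#' @param lambda mean free path (same length unit as r0, r1).
#' @param r0 encounter distance.
#' @param r1 escape distance (r0 < r1 < lambda).
#' @return capture probability in \[0, 1\].
#' @export
capture_probability <- function(f_ass, f_esc, lambda, r0, r1) {
  if (any(r1 <= r0) || any(lambda <= r1))
    stop("need r0 < r1 < lambda")
  if (any(f_ass < 0 | f_ass > 1 | f_esc < 0 | f_esc > 1))
    stop("fractions must lie in [0, 1]")
  p_ass <- 1 - log(lambda / r1) / log(lambda / r0)
  den <- 1 - f_esc * p_ass
  if (any(den <= 0)) stop("inconsistent fractions: denominator <= 0")
  f_ass / den
}

#' Component entry/exit rates from a reduced transition matrix
#'
#' Converts the component-level reduced transition matrix (states: the
#' unbound/encounter state followed by the bound components) into
#' first-order rates, by default as transition probability divided by the
#' lag time, optionally through the exact matrix logarithm (falling back to
#' probability/lag with a warning if the generator has negative
#' off-diagonal entries).  The conventional coarse-grained-time factor
#' (x4 for Martini-derived data) is applied here, once: rates are divided
#' by `time_scale` (so lifetimes are multiplied by it).
#'
#' @param T_cg reduced row-stochastic matrix; row/column 1 is the
#'   unbound/encounter state.
#' @param lag lag time of the matrix (\eqn{\mu}s).
#' @param time_scale time-scale factor (default 4; use 1 for data whose
#'   clock needs no rescaling).
#' @param method "ratio" (probability/lag) or "logm".
#' @param labels optional component labels (length nrow - 1).
#' @return An object of class `component_rates`: data frame with
#'   `component`, `k_enter`, `k_exit` (\eqn{\mu s^{-1}}), plus attributes
#'   `lag`, `time_scale`, `pi_ratio` (bound-to-encounter stationary odds).
#' @export
component_rates <- function(T_cg, lag, time_scale = 4,
                            method = c("ratio", "logm"), labels = NULL) {
  method <- match.arg(method)
  m <- nrow(T_cg)
  if (m < 2) stop("reduced matrix must contain at least one bound component")
  K <- if (method == "logm") {
    G <- tryCatch(pracma::logm(T_cg) / lag, error = function(e) NULL)
    if (is.null(G) || any(G[row(G) != col(G)] < -1e-10)) {
      warning("matrix logarithm is not a valid generator; using ",
              "probability/lag rates")
      T_cg / lag
    } else G
  } else T_cg / lag
  comp <- seq_len(m - 1) + 1
  pi_cg <- stationary_distribution(T_cg)
  out <- data.frame(
    component = labels %||% paste0("comp", seq_len(m - 1)),
    k_enter = K[1, comp] / time_scale,
    k_exit = K[comp, 1] / time_scale)
  structure(out, class = c("component_rates", "data.frame"),
            lag = lag, time_scale = time_scale,
            pi_ratio = pi_cg[comp] / pi_cg[1])
}

#' Per-component dimer lifetimes
#'
#' \eqn{T_{off} = 1 / k_{exit}}; the time-scale factor was already applied
#' by [component_rates()], so no further scaling happens here.
#'
#' @param rates a [component_rates()] object.
#' @return data frame `component`, `k_off`, `T_off` (\eqn{\mu}s; `Inf`
#'   with a warning where `k_exit` is 0).
#' @export
lifetimes <- function(rates) {
  if (any(rates$k_exit == 0))
    warning("components with k_exit = 0 have infinite lifetime")
  data.frame(component = rates$component, k_off = rates$k_exit,
             T_off = 1 / rates$k_exit)
}

#' Reaction-diffusion parameters
#'
#' @param D relative diffusion constant (\eqn{\mu m^2/s}).
#' @param r0 encounter distance (nm).
#' @param r1 escape distance (nm, default 7).
#' @param f_ass,f_esc association/escape fractions at r1 measured from
#'   unbiased trajectories started near r0.
#' @param c_grid 2D concentrations (\eqn{\mu m^{-2}}).
#' @param c_sim concentration of the source simulation (two proteins per
#'   box; \eqn{\mu m^{-2}}), used for consistency checks.
#' @return list of class `rd_params`.
#' @export
rd_params <- function(D = 0.1, r0 = 6.2, r1 = 7,
                      f_ass = 0.5, f_esc = 0.5,
                      c_grid = 10^seq(0, 4, by = 0.25), c_sim = NULL) {
  if (r1 <= r0) stop("need r1 > r0")
  if (D <= 0) stop("D must be positive")
  structure(list(D = D, r0 = r0, r1 = r1, f_ass = f_ass, f_esc = f_esc,
                 c_grid = c_grid, c_sim = c_sim), class = "rd_params")
}

#' Concentration scan of association kinetics and dimer fractions
#'
#' For every concentration, combines the diffusive encounter rate
#' \eqn{k_{+1}(c) c}, the capture probability \eqn{\gamma(c)} and the
#' reaction-limited conversion rates of the components into effective
#' first-order on-rates (the mean-first-passage composite of the two-step
#' scheme, \eqn{k_{on,I} = [1/(\gamma_I k_{+1} c) + 1/k_{enter,I}]^{-1}},
#' which reduces to \eqn{\gamma_I k_{+1} c} at low concentration and
#' saturates at the reaction-limited \eqn{k_{enter,I}} at high
#' concentration), and solves the steady state of the linear scheme
#' unbound <-> encounter <-> component for the equilibrium fractions.
#' Grid points with mean free path \eqn{\lambda \le r_1} are outside the
#' dilute model's validity and are flagged (`valid = FALSE`, NA results).
#'
#' @param rates a [component_rates()] object.
#' @param params an [rd_params()] object.
#' @return An object of class `rd_result`: tidy data frame with one row
#'   per concentration and component: `c`, `component`, `lambda_um`,
#'   `k_plus1_um2_s`, `gamma`, `k_on_first_us` (\eqn{\mu s^{-1}}),
#'   `k_on_second_um2_us` (\eqn{\mu m^2 \mu s^{-1}}), `k_off_us`,
#'   `T_off_us`, `fraction`, `fraction_total_bound`, `valid`.
#' @export
concentration_scan <- function(rates, params) {
  stopifnot(inherits(rates, "component_rates"), inherits(params, "rd_params"))
  ks <- sum(rates$k_enter)
  rows <- list()
  for (c in params$c_grid) {
    lam_um <- mean_free_path(c)
    valid <- lam_um > params$r1 * 1e-3
    if (!valid || ks == 0) {
      gam <- NA_real_; kp1 <- NA_real_
      kon <- rep(if (ks == 0 && valid) 0 else NA_real_, nrow(rates))
      frac <- rep(if (ks == 0 && valid) 0 else NA_real_, nrow(rates))
      if (ks == 0 && valid) {
        kp1 <- k_plus1(c, params$D, params$r0)
        gam <- 0
      }
    } else {
      kp1 <- k_plus1(c, params$D, params$r0)           # um^2/s
      gam <- capture_probability(params$f_ass, params$f_esc,
                                 lam_um, params$r0 * 1e-3,
                                 params$r1 * 1e-3)
      gam_i <- gam * rates$k_enter / ks
      k_enc <- kp1 * c / 1e6                           # first-order, us^-1
      kon <- 1 / (1 / (gam_i * k_enc) + 1 / rates$k_enter)
      # steady state of unbound <-> encounter <-> components
      k_minus1 <- (1 - gam) / gam * ks
      x_enc <- k_enc / k_minus1
      x_comp <- x_enc * rates$k_enter / rates$k_exit
      tot <- 1 + x_enc + sum(x_comp)
      frac <- x_comp / tot
    }
    rows[[length(rows) + 1]] <- data.frame(
      c = c, component = rates$component, lambda_um = lam_um,
      k_plus1_um2_s = kp1, gamma = gam,
      k_on_first_us = kon, k_on_second_um2_us = kon / c,
      k_off_us = rates$k_exit, T_off_us = 1 / rates$k_exit,
      fraction = frac, fraction_total_bound = sum(frac), valid = valid)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("rd_result", "data.frame"), params = params)
}

#' Rate unit conversions
#'
#' Exact power-of-ten conversions between the first-order rate units used
#' in reporting.
#'
#' @param x rates.
#' @param from,to one of "per_us", "per_ms", "per_s".
#' @return converted rates.
#' @export
convert_rate <- function(x, from = "per_us", to = "per_ms") {
  pow <- c(per_us = 6, per_ms = 3, per_s = 0)
  if (!from %in% names(pow) || !to %in% names(pow))
    stop("unknown rate unit")
  x * 10^(pow[[from]] - pow[[to]])
}

#' First-order association rate from a per-concentration rate coefficient
#'
#' Multiplies a second-order 2D rate coefficient (per receptor
#' concentration) by the concentration, e.g. a tabulated
#' \eqn{3\times 10^{-6}\ \mu s^{-1}} per \eqn{\mu m^{-2}} at
#' \eqn{c = 100\ \mu m^{-2}} gives \eqn{3\times 10^{-4}\ \mu s^{-1}} =
#' 0.3 ms\eqn{^{-1}}.
#'
#' @param k_on_per_c second-order coefficient (\eqn{\mu s^{-1}} per
#'   \eqn{\mu m^{-2}}).
#' @param c concentration (\eqn{\mu m^{-2}}).
#' @return first-order rate (\eqn{\mu s^{-1}}).
#' @export
first_order_k_on <- function(k_on_per_c, c) k_on_per_c * c
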