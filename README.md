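# dimerkin

Kinetics of membrane-receptor dimerization from multi-ensemble Markov
state models.

Class-A receptors (the µ-opioid receptor is the motivating case) form
transient homodimers in the membrane.  `dimerkin` turns trajectories of a
protomer pair into the quantities experimentalists ask about — association
rates at a given receptor surface density, per-interface dimer lifetimes,
and equilibrium dimer fractions — through the following chain:

* **Collective variables.** Each frame is reduced to $(d, \alpha_1,
  \alpha_2)$: the inter-protomer COM distance and the two unsigned angles
  between each protomer's TM1 direction and the inter-protomer axis, with
  the periodicity-free 4D embedding $(d\sin\alpha_1, d\cos\alpha_1,
  d\sin\alpha_2, d\cos\alpha_2)$.  Unbiased data are duplicated with
  $\alpha_1 \leftrightarrow \alpha_2$ swapped (the protomers are
  identical).
* **Markov state model.** k-means microstates (plus one reserved state for
  $d \ge L/2$), sliding-window counts, reversible maximum-likelihood
  transition matrix, implied-timescale / Chapman–Kolmogorov validation,
  trajectory bootstrap for uncertainties.
* **TRAM.** Unbiased and umbrella-restrained ensembles are combined with
  the transition-based reweighting analysis method into one unbiased
  stationary distribution and reversible transition matrix; with a single
  unbiased ensemble it reduces exactly to the reversible MLE.
* **Kinetic structure.** PCCA+ metastable clusters; automatic detection of
  the unbound cluster (far, angularly flat); kinetically disconnected
  orientational components C00 / C0π / Cπ0 / Cππ; swap-symmetric
  macrostates; committor-based umbrella-window placement; transition-path
  flux decomposition into pathways.
* **Coarse-graining.** The reduced transfer matrix
  $T^{CG} = I + \mathbf 1\pi_{CG}^\top - H^{-1}$, with $H$ the
  stationary-weighted aggregation of the fundamental matrix
  $(I - T + \mathbf 1\pi^\top)^{-1}$, preserves the full model's
  cross-relaxation behaviour exactly.
* **Interfaces.** Inter-protomer backbone-bead contacts (0.8 nm cutoff),
  dimeric microstates ($P(\ge 10\ \text{contacts}) \ge 0.9$), per-residue
  contact statistics, and interface names in the `TM1,2,(H8)/TM1,2,(H8)`
  style.
* **Reaction–diffusion extrapolation.** The two-step scheme
  $A{+}B \rightleftharpoons A{\cdot}B \rightleftharpoons AB$ with the 2D
  diffusive rate $k_{+1} = 4\pi D/\ln(\lambda/r_0)$,
  $\lambda = (\pi c)^{-1/2}$, and the Northrup–Allison–McCammon capture
  probability $\gamma = f_{ass}/(1 - f_{esc}p_{ass})$ yields
  $k_{on}(c)$, $k_{off}$, lifetimes and dimer fractions per component at
  arbitrary surface density $c$.

Because multi-millisecond coarse-grained MD is not reproducible at desk
scale, the package includes a first-class synthetic-data module: Brownian
dynamics of two orientable protomers in a periodic membrane patch, with
binding wells carved through a steric wall (so re-orientation in contact
is forbidden, as for real receptors), plus umbrella-restrained
counterparts and discrete Markov ground truths with known bias energies.
Every pipeline stage is tested against independent oracles on these
systems.  See the vignette (`vignettes/dimerization-kinetics.Rmd`) for the
model details and design choices.

## Worked example

```r
library(dimerkin)

world <- mor_like_world(seed = 1)   # four bound basins, steric wall
res <- run_dimer_pipeline(world, n_traj = 16, n_steps = 30000, stride = 5,
                          lag = 20, n_centers = 80, n_umbrella = 8,
                          umbrella_steps = 4000, seed = 42,
                          c_grid = c(1, 10, 100, 1000, 5000))

res$decomp_tram$labels
#> [1] "Cpi0"  "C0pi"  "Cpipi" "C00"
round(res$decomp_tram$weights, 3)
#> [1] 0.119 0.118 0.044 0.036
round(res$r0, 2)
#> [1] 6.21
cbind(res$rates, T_off_us = round(1 / res$rates$k_exit, 2))
#>   component k_enter k_exit T_off_us
#> 4      Cpi0  0.0940  0.539     1.85
#> 3      C0pi  0.0944  0.545     1.83
#> 2     Cpipi  0.0564  0.877     1.14
#> 1       C00  0.0680  1.302     0.77
subset(res$scan, valid & component == "C0pi",
       c(c, gamma, k_on_first_us, fraction_total_bound))
#>     c gamma k_on_first_us fraction_total_bound
#>     1 0.150      1.26e-06             7.29e-06
#>    10 0.151      1.71e-05             9.87e-05
#>   100 0.154      2.63e-04             1.53e-03
#>  1000 0.162      5.49e-03             3.09e-02
#>  5000 0.250      6.30e-02             2.52e-01
```

Reading the output: the four orientational components are detected with
the asymmetric pair dominant (population 0.119 + 0.118 of the stationary
distribution at the simulated density); the encounter radius is the mean
unbound distance $r_0 = 6.21$ nm; entry/exit rates are in µs⁻¹, so the
asymmetric dimer lifetime is ≈1.8 µs in this shallow desk-scale system;
the concentration scan shows the association rate vanishing at low
density ($k_{on} \approx 0$ below $10^2\,\mu m^{-2}$) and climbing toward
the reaction-limited plateau ($k_{enter} \approx 0.094\ \mu s^{-1}$) at
high density, with the total bound fraction rising monotonically.
Interface labels for the macrostates are in
`res$contacts$interface`, e.g.
`"N-term,TM1,(IL1),TM2,(EL1),H8,C-term/N-term,TM1,2,7,H8,C-term"` for a
symmetric α≈0 face dimer.

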