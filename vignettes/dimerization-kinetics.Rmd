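---
title: "Modelling membrane-receptor dimerization kinetics with dimerkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling membrane-receptor dimerization kinetics with dimerkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerkin)
```

## The problem

Class-A membrane receptors such as the opioid receptors form transient
homodimers in the plasma membrane.  Whether those dimers matter
physiologically depends on quantities that are hard to measure directly:
the association rate at a given receptor surface density, the lifetime of
each dimer interface, and the equilibrium dimer fraction.  `dimerkin`
implements a complete analysis chain that extracts these quantities from
trajectories of a pair of protomers diffusing in a membrane:

1. describe each frame by the order parameter $(d, \alpha_1, \alpha_2)$ —
   the inter-protomer centre-of-mass distance and the two unsigned angles
   between each protomer's TM1 direction and the line connecting the two
   protomers;
2. discretize the 4D embedding
   $(d\sin\alpha_1, d\cos\alpha_1, d\sin\alpha_2, d\cos\alpha_2)$ into
   microstates by k-means and estimate a reversible Markov state model
   (MSM);
3. combine unbiased and umbrella-restrained ensembles with the
   transition-based reweighting analysis method (TRAM);
4. cluster the microstates into metastable sets (PCCA+), identify the
   unbound cluster and the kinetically disconnected orientational
   components, and coarse-grain the transfer matrix while preserving the
   full model's cross-relaxation behaviour;
5. characterize dimer interfaces by inter-protomer backbone-bead contact
   statistics;
6. extrapolate the association kinetics to arbitrary 2D receptor
   concentrations with a two-step reaction–diffusion model.

Because the molecular-dynamics data such an analysis normally consumes are
far beyond desk scale, the package ships a synthetic-data module that
generates Brownian-dynamics trajectories of a reduced two-protomer system
with known ground truth, so that every stage of the pipeline is testable
against independent oracles.

## The synthetic world

`synthetic_world()` reduces each protomer to an orientable point in a
periodic square membrane patch.  The interaction potential lives on
$(d, \alpha_1, \alpha_2)$ and consists of Gaussian binding wells carved
through a short-range exponential steric wall.  Dynamics are overdamped
Langevin (Euler–Maruyama) on the underlying positions and orientations —
never directly on the non-Euclidean $(d, \alpha)$ space — with reflecting
behaviour supplied by box periodicity.

The default study conditions were chosen once, from the physical scales of
coarse-grained receptor simulations, and are not tuned per analysis:

* **Box side 15 nm** — the membrane patch of a typical two-receptor
  simulation box, giving a simulated surface density of
  $2/L^2 \approx 8.9\times10^3\,\mu m^{-2}$.
* **Translational diffusion 5 nm²/µs per protomer** (relative
  $D = 10$ nm²/µs $= 10\,\mu m^2/s$), the unscaled mobility of a small
  membrane protein in a coarse-grained lipid bilayer.
* **Rotational diffusion 0.3 rad²/µs.**  In-plane rotation of a ~2 nm
  receptor in a bilayer is much slower than translation; an unphysically
  fast rotational mobility lets a protomer re-orient during a brief
  unbinding excursion, which destroys the kinetic separation between
  orientational components that real receptors show.
* **Binding wells at $d = 3$ nm**, widths 0.4 nm and 0.5 rad, one well per
  orientational combination of the two interface faces
  ($\alpha \approx 0$: the TM1/TM2/H8 face; $\alpha \approx \pi$: the
  TM4/TM5/TM6 face).  Raw depths of 10.5–11.5 kT against a 6 kT wall give
  effective binding energies of ~4.5–5.5 kT and dimer lifetimes of a few
  microseconds — deep enough for clean metastability, shallow enough that
  unbiased desk-scale sampling still sees many binding/unbinding events.
* **The steric wall** ($h\,e^{-(d-3)/0.3}$ kT) is the synthetic analogue of
  excluded volume: two protomers in contact cannot rotate past each other,
  so interconversion between orientational components requires passage
  through the unbound state.  This is the single most important feature
  the generator must reproduce; without it the component decomposition
  degenerates.
* **Time step 0.5 ns**, so per-step displacements (~0.07 nm) stay far below
  the well widths; umbrella restraints default to
  $k_d \approx 97\,kT/\mathrm{nm}^2$ and
  $k_\alpha \approx 39\,kT/\mathrm{rad}^2$, the reduced-unit equivalents of
  250 kJ/mol/nm² and 100 kJ/mol at 310 K.

What the generator does *not* emulate: internal receptor conformational
dynamics, lipid-mediated interactions, hydrodynamic coupling, and
thermostat artefacts of molecular-dynamics engines.  Tests passing on the
synthetic system therefore validate the *statistical machinery* — not any
claim about a specific receptor.

## Markov state modelling

Frames with $d \ge L/2$ are assigned to one reserved unbound microstate;
everything else is clustered by k-means (k-means++ seeding, Lloyd
iterations, fixed seed) in the 4D embedding, which removes angular
periodicity at the cost of compressing angular resolution at small $d$ —
exactly where orientation matters least.  Transition counts use a sliding
window and never cross trajectory boundaries.  The reversible
maximum-likelihood transition matrix is obtained by the standard
self-consistent flux iteration; we stop on both a relative log-likelihood
change ($10^{-10}$) and a maximum transition-probability change
($10^{-12}$), because the likelihood plateaus long before the slow
stationary components stop moving.  Estimation is restricted to the
largest connected set of the count support, and dropped states are
reported.

Validation follows the standard MSM playbook: implied timescales
$t_i = -\tau/\ln\lambda_i$ compared across lags, Chapman–Kolmogorov tests
on metastable sets, and uncertainties from bootstrapping whole
trajectories (mean and 5%/95% percentiles).

## Protomer exchange symmetry

The two protomers are identical, so every unbiased trajectory is
duplicated with $\alpha_1 \leftrightarrow \alpha_2$ swapped.  All
downstream statistics are then exactly symmetric under protomer exchange;
the suite checks that the count matrix is invariant under the microstate
relabelling induced by the swap.  A practical consequence of this symmetry
is spectral degeneracy: the mirror-image components relax on identical
timescales, and PCCA+ memberships computed from a degenerate eigenpair can
lump mirror basins at small cluster numbers.  The unbound-cluster scan
(below) therefore accepts a floor on the number of clusters.

## TRAM

The multi-ensemble estimator solves the self-consistent equations
(per-ensemble state free energies $f_i^k$ and Lagrange multipliers
$\nu_i^k$)

$$p^k_{ij} = \frac{(c^k_{ij}+c^k_{ji})\,e^{-f^k_j}}
  {\nu^k_i e^{-f^k_j} + \nu^k_j e^{-f^k_i}}, \qquad
  \sum_j p^k_{ij} = 1,$$
$$e^{-f^k_i} = \sum_{x\in X_i} \mu(x)\,e^{-b^k(x)}, \qquad
  \mu(x) = \Big(\sum_l R^l_{s(x)}\,e^{f^l_{s(x)} - b^l(x)}\Big)^{-1},
  \qquad R^k_i = N^k_i + \sum_j c^k_{ij} - \nu^k_i,$$

iterated in log space until the largest free-energy change falls below the
tolerance (default $10^{-9}$ kT; tightening to $10^{-12}$ does not move the
result measurably).  Free energies are gauge-fixed so the unbiased state
weights sum to one.  With a single unbiased ensemble the fixed point is
exactly the reversible MLE, which the suite asserts to $10^{-8}$.  Because
no independent TRAM implementation is available in this environment, the
estimator is additionally cross-checked against an MBAR-style
thermodynamic-only estimator (written in the test suite) and against
planted discrete truths with known bias energies.

Two numerical details matter.  First, bias energies are evaluated from each
frame's collective variables for *every* ensemble, which keeps biased
synthetic data self-contained.  Second, when frames are strided to reduce
cost, each kept frame carries a multiplicity equal to the stride so that
the frame-likelihood and transition-likelihood parts of the estimator see
consistent totals; without this the visitation weights $R^k_i$ lose their
positivity margin and the iteration can oscillate.

Before TRAM, microstates of the preliminary unbound component that show no
exchange with the rest of the system in the count matrix are re-clustered
into a smaller centre set (default one centre per seven silent states),
mirroring the usual practice of not spending model resolution on pure
diffusion far from contact.

## Unbound cluster, components, macrostates

The unbound cluster is found by scanning the PCCA+ cluster number upward
and accepting the smallest value for which some cluster contains only
microstates with $d > 4.2$ nm and an angularly flat population
(operationalized as: population-weighted circular resultant length of the
member angles below 0.3, with at least three of the four angular quadrants
occupied — the criterion is stated qualitatively in the literature, so the
numbers are package conventions).  Removing that cluster and taking
connected components of the remaining clusters on the *support* of the
inter-cluster counts yields the kinetically disconnected components.
Components are labelled C00, C0π, Cπ0 or Cππ by the population-weighted
mean angles, using windows of half-width $\pi/4$ around 0 and $\pi$;
anything else is labelled "other".  Macrostates merge each bound cluster
with its swap mirror image (found by mapping member centres through the
swap and re-assigning); mirrors of asymmetric clusters live in the opposite
asymmetric component, so those macrostates span the C0π/Cπ0 pair.

## Coarse-graining

The reduced transfer matrix imposes the cross-relaxation behaviour of the
microscopic model.  With the fundamental matrix
$Z = (I - T + \mathbf 1\pi^\top)^{-1}$ and
$H_{JI} = \sum_{j\in J, i\in I}\pi_j Z_{ji}/\pi^{CG}_J$, the coarse matrix
is $T^{CG} = I + \mathbf 1 \pi_{CG}^\top - H^{-1}$.  This construction is
exactly row-stochastic and leaves the aggregated stationary vector exactly
stationary for *any* partition (the suite verifies both to machine
precision on random unequal partitions, and verifies that the slow
eigenvalues of a metastable partition are preserved exactly — which the
naive local-equilibrium projection does not achieve).  Printed forms of
this construction are ambiguous between row- and column-stochastic index
conventions; the implementation fixes the convention by requiring these
structural identities rather than by assumption.  For exactly
decoupled chains the fundamental matrix is singular; closed communicating
classes are then coarse-grained separately and are absorbing at the coarse
level.  Estimated (noisy) matrices can produce slightly negative coarse
entries; beyond $10^{-8}$ the exported function treats the partition as
kinetically inconsistent, while the pipeline tolerates noise-level
negatives up to $10^{-2}$, clipping and renormalizing.

## Transition-path analysis and umbrella placement

Forward committors solve the standard linear system; reactive fluxes
$F_{ij} = \pi_i(1-q_i)T_{ij}q_j$ are antisymmetrized and decomposed into
pathways by repeatedly removing the widest (maximum-bottleneck) path.
Umbrella windows are placed at microstate centres whose committor from the
unbound state to each component's most probable microstate exceeds 0.1 —
i.e. along the binding channels, where unbiased sampling is thinnest.

## Contacts and interface naming

A residue pair (one residue per protomer) is in contact when any of its
backbone-bead pairs lies below 0.8 nm (minimal image).  Per microstate,
$p^{Tot}(n)$ is the probability of at least $n$ inter-protomer contacts and
$p^{Micro}(i,j)$ the per-pair contact probability, both averaged over
unbiased frames only; a microstate is *dimeric* when
$p^{Tot}(10) \ge 0.9$.  Macrostate contact maps are stationary-weighted
sums over dimeric member microstates; we report both the raw weighted sum
and the normalized version (divided by the summed dimeric weight) and use
the normalized one for naming, so that labels are comparable between
macrostates of different population.  In an interface label a region
appears in full when its expected contact count exceeds three and in
parentheses otherwise (a count of exactly three is parenthetical — the
source convention leaves that case open); consecutive TM helices collapse
("TM1,2"), and the two sides are joined in lexicographic order.

For synthetic data, protomers are decorated with one backbone bead per
residue (residues 65–352 of a generic 7TM receptor layout, helices on a
ring of radius 1.3 nm with the TM1/TM2/H8 face at azimuth 0).  The
template is quasi-two-dimensional — all beads in the membrane plane — so
that rigid-body decoration of a frame round-trips exactly through the 3D
angle definition; genuinely three-dimensional bead frames are exercised in
the unit tests.

## Reaction–diffusion extrapolation

The two-step scheme $A+B \rightleftharpoons A{\cdot}B \rightleftharpoons
AB$ separates diffusion from binding.  The encounter complex $A{\cdot}B$
is identified with the model's unbound cluster, whose population-weighted
mean distance gives the encounter radius $r_0$.  The 2D diffusive rate
coefficient is $k_{+1} = 4\pi D/\ln(\lambda/r_0)$ with mean free path
$\lambda = (\pi c)^{-1/2}$ — valid while $\lambda > r_1 > r_0$; grid
points outside that window are flagged rather than extrapolated.  The
capture probability follows the Northrup–Allison–McCammon closure
$\gamma = f_{ass}/(1 - f_{esc}\,p_{ass})$ with
$p_{ass} = 1 - \ln(\lambda/r_1)/\ln(\lambda/r_0)$, where $f_{ass}$ and
$f_{esc} = 1 - f_{ass}$ are measured from unbiased trajectories as the
fractions of encounter episodes (started at $r_0$) that bind before
reaching the escape distance $r_1$.

Component entry and exit rates come from the component-level reduced
matrix as probability/lag (with an exact matrix-logarithm option that
falls back with a warning when the logarithm is not a valid generator).
The effective first-order on-rate per component is the mean-first-passage
composite of the two-step scheme,

$$k_{on,I}(c) = \Big(\frac{1}{\gamma_I(c)\,k_{+1}(c)\,c} +
  \frac{1}{k_{enter,I}}\Big)^{-1},
  \qquad \gamma_I = \gamma\,\frac{k_{enter,I}}{\sum_J k_{enter,J}},$$

which reduces to the diffusion-limited $\gamma_I k_{+1} c$ at low density
and saturates at the reaction-limited $k_{enter,I}$ at high density —
the qualitative shape seen in surface-density scans of receptor
dimerization.  A pure $\gamma k_{+1} c$ expression cannot saturate inside
the validity window of the dilute formula, which is why the composite is
used.  Equilibrium fractions solve the steady state of the full linear
scheme (unbound ⇌ encounter ⇌ each component), whose bound-to-encounter
ratios automatically reproduce the source model's stationary odds.  The
conventional coarse-grained-time factor (×4 for Martini-derived data) is
applied exactly once, in `component_rates()`, and defaults to 1 for
synthetic data whose clock needs no rescaling.

## Problem sizes and numerical conventions

The shipped analyses and tests run the pipeline at desk scale: 20 unbiased
trajectories of 30 µs (60,000 steps recorded every 2.5 ns) — individual
trajectories must be long against the ~2 µs dimer lifetime and the
ensemble must contain on the order of a hundred binding events before
stationary weights are testable — 80 k-means
microstates, a 50 ns lag, 8 umbrella windows of 2 µs, TRAM at tolerance
$10^{-9}$ kT with stride 2–5, and 10 bootstrap replicates (solved at a
slightly relaxed tolerance of $10^{-7}$ kT, which is far below the
statistical spread the bootstrap measures).  Eigenvalues are sorted by
modulus with ties broken by real part; crisp PCCA+ assignment is the
membership argmax with ties to the lower cluster index; k-means uses at
most 500 Lloyd iterations.  Angles are unsigned three-point angles in
$[0, \pi]$ computed in full 3D by default, with a membrane-plane
projection available as an option.

## Known limitations

* The synthetic world has no internal protomer dynamics, so
  "conformational coupling" questions are out of reach by design.
* Component detection judges connectivity on raw count support; a single
  spurious transition (e.g. from an unbinding/rebinding event inside one
  lag window) merges two components.  The physical separation of
  timescales — slow rotation, steric locking — is what makes the
  decomposition stable, and the generator defaults respect it.
* The reaction–diffusion extrapolation inherits the dilute-2D assumptions
  of the $k_{+1}$ formula and is flagged invalid once the mean free path
  approaches the escape radius.
* Bootstrap intervals resample whole trajectories; with few, long
  trajectories they are wide, which is honest but blunt.
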