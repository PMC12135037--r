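---
title: "Modelling cation redistribution in plasma-treated seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cation redistribution in plasma-treated seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionseed)
```

## The physical picture

Cold atmospheric plasma treatment of seeds improves germination, and one
candidate mechanism is electrostatic: electrons in the plasma sheath are far
more mobile than positive species, so a treated surface accumulates net
negative charge. Mobile cations inside the seed (K⁺, Ca²⁺, Na⁺) then feel an
attraction toward the surface, and depth-resolved surface spectroscopy of
treated seeds indeed shows enrichment of these elements in the outer hull
layers. `ionseed` implements both halves of that argument:

* a minimal, fully specified electrostatic model of the redistribution,
  sampled with a Metropolis Monte Carlo algorithm, and
* the reduction of XPS gas-cluster-ion-beam (GCIB) depth profiles that
  provides the experimental evidence (etch-depth calibration, silicate
  oxygen correction, element ratios, treated-versus-control comparison).

## The disk model

The seed is a two-dimensional disk of radius $R$ containing $N$ mobile point
cations of charge $q$. Before treatment the seed is neutral: a uniform
background density $\sigma = -Nq/(\pi R^2)$ spreads over the disk. The
plasma deposits $N_\mathrm{ext}$ fixed point charges $Q_\mathrm{ext} < 0$ at
uniformly random angles exactly on the perimeter (charge concentrates at
surface asperities, so a small number of strong point sites is the natural
idealisation). The internal energy of a configuration is a sum over ions of
three Coulomb terms (with $k = (4\pi\epsilon_0)^{-1}$):

* ion–site: $U_1^{(i)} = k\,Q_\mathrm{ext}\,q \sum_j 1/|\vec r_i - \vec R_j|$,
* ion–ion: $U_2^{(i)} = \tfrac{k q^2}{2} \sum_{j\ne i} 1/|\vec r_i - \vec r_j|$
  (the half cancels double counting when summed over $i$; the package's
  `energy_u2()` counts each pair once),
* ion–background: $U_3^{(i)} = q\,V(\rho_i)$, where $V$ is the in-plane
  potential of the uniformly charged disk,
  $V(\rho) = \sigma R\,E(\rho/R)/(\pi \epsilon_0)$, with $E$ the complete
  elliptic integral of the second kind — evaluated by Carlson's duplication
  algorithm and cross-checked in the tests against an independent
  implementation and against direct 2D quadrature of the Coulomb kernel.

Interactions among the fixed negative charges (site–site, site–background)
are constant during sampling and are omitted throughout: Metropolis
decisions depend only on energy differences.

At fixed temperature the equilibrium distribution is canonical,
$\rho \propto e^{-U/k_BT}$, and that is the sampler's target. Hindered
diffusion through seed tissue is modelled by an activation energy $E_0$
paid per boundary of the $M$ concentric equal-area cells a move crosses.
Because the crossing count is symmetric under reversal, the barrier factor
$e^{-E_0 n_\times / k_B T}$ multiplies a standard Metropolis acceptance and
preserves detailed balance exactly: the barrier changes the dynamics (how
fast radial transport happens), never the equilibrium. The tests verify
this directly by comparing sampled single-particle densities with
grid-integrated Boltzmann densities at $E_0 = 0$ and $E_0 = 4k_BT$.

### Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `n_ions` | mobile cations $N$ | 1000 | reference scenario |
| `ion_charge` | $q$ | $e$ | one elementary charge; the effective charge of a hydrated cation in tissue is not better constrained |
| `n_ext_sites` | perimeter sites $N_\mathrm{ext}$ | 10 | few strong sites (asperity charging) |
| `site_charge` | $Q_\mathrm{ext}$ per site | $-4\times10^5\,e$ | reference scenario, per-site reading (see below) |
| `radius` | $R$ | 1 mm | reference scenario |
| `temperature` | $T$ | 300 K | room temperature |
| `barrier` | $E_0$ | $4k_BT$ | equivalent potential $E_0/e \approx 0.103$ V, the order of a plant resting membrane potential |
| `n_rings` | equal-area cells $M$ | 20 | radial resolution of profiles and barrier granularity |
| `step_size` | proposal radius | $R/50$ | acceptance in a healthy range for near-uniform states; a monitor warns outside [0.1, 0.7] |
| `min_separation` | singularity guard | $10^{-6}R$ | proposals bringing two charges closer are rejected, so the Hamiltonian is exact on the admissible set (no kernel softening) |

One *iteration* is one attempted single-ion move, with the ion chosen
uniformly at random; sweep-based counting would multiply all iteration
numbers by $N$. Runs are bit-reproducible: a seed `s` drives setup via
`set.seed(s)` and the dynamics via `set.seed(s + 1)`, so the number of
setup draws cannot perturb the dynamics stream.

### The strong-binding regime and the charge-reading sensitivity scan

The reference charges place the model deep in a strong-binding regime: the
mean ion–site energy of a random configuration is
$k q Q_\mathrm{ext} \cdot 4 N_\mathrm{ext}/(\pi R) \approx -1.17\times10^{-18}$ J/ion,
about $-283\,k_BT$. Thermal motion is then a perturbation; at equilibrium
the cations collapse into tight clusters around the perimeter sites and the
acceptance rate decays toward zero as clusters compact. Two points follow:

* The magnitude of every energy in the model scales with the product
  $q\,Q_\mathrm{ext}$, and "$-4\times10^5$ elementary charges" admits two
  readings — per site, or in total over the ten sites.
  `initial_energy_scan()` therefore reports the initial-state energy under
  both readings side by side, together with the closed-form expectation of
  the dominant term as a cross-check. Conclusions about *enrichment* are
  robust across the readings; absolute energies are not.
* A true thermal-equilibrium plateau is replaced, in this regime, by a
  freezing of the cluster state: the energy trace stabilises when the
  clusters stop evolving on the sampled timescale. `detect_convergence()`
  (consecutive window means within `rel_tol = 1e-4`, windows of $10^4$
  iterations) fires on that plateau, at a few times $10^6$ attempted moves
  under the defaults.

With 3D Coulomb attraction to a point charge at 300 K there is no
intermediate regime to tune into: the thermal length
$k q |Q_\mathrm{ext}|/(k_B T)$ spans decades, so an on-rim attractor with
$|Q_\mathrm{ext}| \ge e$ binds at the `min_separation` scale, while a much
weaker one is invisible. This is a property of the model, not of the
sampler, and it is why the sampler's exactness is validated on a separate,
smooth scenario (below).

### Sampler validation

`run_mc()` is validated against brute-force oracles in the test suite:

* *Energetics.* Total energies against a triple-loop sum; incremental
  single-move differences against full recomputation (relative error below
  $10^{-12}$ over $10^3$ random moves); a running-energy drift check against
  a final recompute after every run.
* *Equilibrium.* A single-particle scenario with a smooth Hamiltonian — a
  strongly confining background bowl ($\sigma = -1.84\times10^{-9}$ C m⁻²,
  giving a $\sim 4\,k_BT$ potential range across the disk) plus one fixed
  charge of $-8\times10^4\,e$ placed *outside* the disk at $(2R, 0)$ for
  angular structure. This synthetic fixture avoids the point-attractor
  collapse while exercising every energy term. The sampled occupancy on a
  20 × 16 polar grid is compared with the Boltzmann density integrated on a
  200 × 192 grid; total-variation distance stays below 0.01 (bound 0.05)
  both without the barrier and with $E_0 = 4 k_B T$.

### Observables

Radial profiles count ions per equal-area ring, averaged over post-burn-in
configurations sampled every $10^3$ iterations (a decorrelation gap), and
divide by ring area; the uniform reference $Nq/(\pi R^2)$ — whose magnitude
equals $|\sigma|$ by neutrality — is the concentration of the untreated
state. Profiles conserve total charge to machine precision by construction,
and `enrichment_ratio()` (outermost rings over the reference) summarises
surface accumulation: above 1 with perimeter charge, compatible with 1
without it. Equilibrium energies carry batch-means standard errors, because
consecutive recordings are autocorrelated.

## XPS depth-profile reduction

Depth is calibrated linearly from etch cycles: protocol "a" (300-atom Ar
clusters, 8 keV) removes 6.7 nm per cycle, protocol "b" (1000-atom
clusters, 6 keV after a brief monatomic pre-sputter) 21.6 nm per cycle.
The pre-sputtered thickness is not quantified, so protocol-b depths are
relative to the pre-etched surface and flagged as such. Because silicate
agglomerates on the seed surface contribute to the O 1s signal, organic
oxygen is estimated as $O - 2\,\mathrm{Si}$ (an assumed SiO₂ stoichiometry
— a simplification, since Si–C–O structures also occur; the factor is
configurable for sensitivity analyses). The correction is clamped at zero
and clamping events are flagged, never silently dropped.
Treated-versus-control comparison interpolates the treated profile linearly
onto the control depth grid, strictly within the overlapping range, and
reports depth-averaged ratios and the fraction of depths with treated
above control (ties count one half).

## The synthetic-data generator

No machine-readable depth profiles accompany the measurements, so the
generator emulates their statistical structure: element $e$ at depth $z$
has expected atomic % $b_e + a_e\,e^{-z/\lambda_e}$, carbon acts as the
compositional balance (surface enrichment of minority elements is mirrored
by carbon depletion), and each cell receives mean-one multiplicative
lognormal noise — chosen because atomic percentages are positive and
instrument noise is roughly proportional — before rows are renormalised to
100. Defaults anchor the baseline to the measured control surface
composition and the amplitudes to the treated-minus-control surface
difference, with decay lengths of 100 nm for K, Ca and N (enrichment
persists across the profiled depth) and 80 nm for O. Parameter recovery by
nonlinear least squares is unbiased within three standard errors across
100 noisy replicates at 5 % noise.

What the generator does *not* emulate — peak-fitting ambiguity,
preferential sputtering, sputter-rate drift, matrix effects on relative
sensitivity factors — bounds what passing tests show about real data: the
reduction pipeline is exact on its stated model, not validated against
instrumental artefacts.

## Problem sizes

The test suite and the acceptance script use: reference-scenario runs of
$1.2\times10^7$ attempted moves (five seeds for the stabilisation
statistic), single-particle validation runs of $5\times10^6$–$2\times10^7$
moves, $10^3$ random moves for the incremental-energy check, 50 radial
points for the potential quadrature, and 100 generator seeds for parameter
recovery. These sizes give each statistic a comfortable margin relative to
its acceptance bound on a single CPU.

## Known limitations

* 2D geometry with a 3D Coulomb kernel; no dielectric contrast or image
  charges; no mobile anions.
* Absolute energies and the iteration count at stabilisation depend
  steeply on the assumed charge magnitudes (see the sensitivity scan);
  only the qualitative surface-enrichment prediction is robust.
* Cell-boundary hopping is a caricature of hindered diffusion: it slows
  radial transport uniformly rather than modelling tissue microstructure.
* The model's length scale (enrichment over hundreds of microns) and the
  XPS probe (hundreds of nanometres) differ by orders of magnitude; the
  simulation is a qualitative analogue of the measured enrichment, not a
  quantitative prediction of it.
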